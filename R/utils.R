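#' Emit a log message to stderr
#'
#' Messages at a level below the active threshold (option
#' `hgtsieve.log_level`, one of "debug", "info", "warn"; default "info")
#' are suppressed.
#'
#' @param level one of "debug", "info", "warn"
#' @param ... message parts, passed to [sprintf()] when `...` has length > 1
#' @return invisibly, the message (or NULL if suppressed)
#' @export
hgt_log <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- getOption("hgtsieve.log_level", "info")
  if (levels[[level]] < levels[[threshold]]) return(invisible(NULL))
  parts <- list(...)
  msg <- if (length(parts) > 1L) do.call(sprintf, parts) else as.character(parts[[1L]])
  message(sprintf("[%s] %s", toupper(level), msg))
  invisible(msg)
}

#' Write a data frame as a tab-separated table
#'
#' All pipeline tables are tab-separated with a single header line and unix
#' line endings, so outputs are bit-exact and diff-able.
#'
#' @param x a data frame
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "NA"
    v
  }
  writeLines(paste(names(x), collapse = "\t"), con, sep = "\n")
  if (nrow(x) > 0L) {
    cols <- lapply(x, esc)
    lines <- do.call(paste, c(cols, sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path
#' @return a data frame
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "")
}

# recursive list merge used by the config reader
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
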