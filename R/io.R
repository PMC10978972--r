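#' Sequence collections
#'
#' A `bio_seqs` object is a named character vector of residues with an
#' `alphabet` attribute ("protein" or "dna"). Identifiers must be non-empty
#' and unique; residues must be non-empty and drawn from the declared
#' alphabet. DNA ambiguity codes (IUPAC) are permitted on construction and
#' flagged via the `ambiguous` attribute; downstream screens, not the
#' reader, decide what to do with them.
#'
#' @param x named character vector of residues
#' @param alphabet "protein" or "dna"
#' @param descriptions optional character vector of free-text descriptions
#' @return a `bio_seqs` object
#' @export
bio_seqs <- function(x, alphabet = c("protein", "dna"), descriptions = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(x) == 0L) {
    return(structure(stats::setNames(character(0), character(0)),
                     alphabet = alphabet, ambiguous = logical(0),
                     descriptions = descriptions, class = "bio_seqs"))
  }
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("every sequence must have a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  x <- toupper(as.character(x))
  names(x) <- ids
  if (any(!nzchar(x))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(x)], collapse = ", "), call. = FALSE)
  }
  allowed <- if (alphabet == "protein") {
    "^[ACDEFGHIKLMNPQRSTVWYBJZXU*]+$"
  } else {
    "^[ACGTNRYSWKMBDHV]+$"
  }
  bad <- !grepl(allowed, x)
  if (any(bad)) {
    stop("residues outside the ", alphabet, " alphabet in: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  ambiguous <- if (alphabet == "dna") grepl("[^ACGT]", x) else grepl("[BJZXU*]", x)
  structure(x, alphabet = alphabet, ambiguous = ambiguous,
            descriptions = descriptions, class = "bio_seqs")
}

#' @export
print.bio_seqs <- function(x, ...) {
  cat(sprintf("bio_seqs: %d %s sequence(s), widths %d-%d\n", length(x),
              attr(x, "alphabet"), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' @export
`[.bio_seqs` <- function(x, i) {
  y <- unclass(x)[i]
  structure(y, alphabet = attr(x, "alphabet"),
            ambiguous = attr(x, "ambiguous")[i], class = "bio_seqs")
}

#' Read a FASTA file
#'
#' Record order is preserved; duplicate identifiers are rejected. The
#' identifier is the first whitespace-delimited token of the header; the
#' remainder is kept as the description.
#'
#' @param path FASTA file
#' @param alphabet "protein" or "dna"
#' @return a [bio_seqs] collection
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA parse error in ", path,
                              ": no records", call. = FALSE)
  if (any(Biostrings::width(set) == 0L)) {
    empty <- which(Biostrings::width(set) == 0L)[1L]
    hdr <- names(set)[empty]
    lines <- readLines(path, warn = FALSE)
    at <- which(lines == paste0(">", hdr))[1L]
    stop(sprintf("FASTA parse error in %s: empty record '%s' (line %s)",
                 path, hdr, ifelse(is.na(at), "?", at)), call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  names(seqs) <- ids
  bio_seqs(seqs, alphabet = alphabet, descriptions = desc)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 80 columns; output is byte-deterministic so that
#' `read_fasta(write_fasta(x))` round-trips exactly.
#'
#' @param seqs a [bio_seqs] collection
#' @param path output file
#' @param width line width for wrapping
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- unclass(seqs)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Default reference-database partitions
#'
#' The partition labels used by the taxonomy loader when none are supplied:
#' the fungal ingroup database (Fungi excluding Neocallimastigomycota) and
#' the non-fungal outgroup databases.
#'
#' @return character vector of partition labels
#' @export
default_partitions <- function() {
  c("Bacteria", "Archaea", "Viruses", "Viridiplantae", "Metazoa",
    "OtherEukaryota", "Fungi")
}

#' Load a taxonomy table
#'
#' Tab-separated with a single header line and columns `id`, `partition`,
#' `kingdom`, `phylum_or_class`. Each row becomes a lineage record; rows
#' whose partition is not among `partitions` are rejected.
#'
#' @param path TSV file
#' @param partitions allowed partition labels
#' @return data frame with columns id, partition, kingdom, phylum_or_class
#' @export
load_taxonomy <- function(path, partitions = default_partitions()) {
  tab <- read_tsv(path)
  need <- c("id", "partition", "kingdom", "phylum_or_class")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("taxonomy schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !(tab$partition %in% partitions)
  if (any(bad)) {
    stop("taxonomy schema error: unknown partition label(s) ",
         paste(unique(tab$partition[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$kingdom) | !nzchar(tab$kingdom))) {
    stop("taxonomy schema error: kingdom rank must be present for every row",
         call. = FALSE)
  }
  tab[, need]
}

#' Build a partitioned reference database
#'
#' Couples one partition's sequences with their taxonomy. Every sequence id
#' must have a taxonomy entry carrying this partition's label.
#'
#' @param partition partition label
#' @param sequences a [bio_seqs] collection
#' @param taxonomy taxonomy data frame (see [load_taxonomy()])
#' @return a `reference_db` object
#' @export
reference_db <- function(partition, sequences, taxonomy) {
  tax <- taxonomy[taxonomy$id %in% names(sequences), , drop = FALSE]
  missing <- setdiff(names(sequences), tax$id)
  if (length(missing) > 0L) {
    stop("no taxonomy entry for sequence(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(tax$partition != partition)) {
    stop("taxonomy entries must all carry partition '", partition, "'",
         call. = FALSE)
  }
  structure(list(partition = partition, sequences = sequences,
                 taxonomy = tax),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db '%s': %d sequences\n", x$partition,
              length(x$sequences)))
  invisible(x)
}

#' Assemble a transcriptome catalog
#'
#' Maps assemblies to genera and holds each assembly's predicted peptides
#' plus (externally produced) per-transcript annotations. Genus and assembly
#' membership come only from this catalog, never from sequence identifiers.
#'
#' @param assemblies data frame with columns `assembly_id`, `genus`
#' @param transcripts named list (by assembly id) of [bio_seqs]
#' @param annotations data frame with column `transcript_id` plus any of
#'   `function_label`, `cog_class`, `cazy_family`, `localization`, `domains`
#' @return an `assembly_catalog` object
#' @export
assembly_catalog <- function(assemblies, transcripts, annotations = NULL) {
  stopifnot(all(c("assembly_id", "genus") %in% names(assemblies)))
  if (anyDuplicated(assemblies$assembly_id)) {
    stop("each assembly must map to exactly one genus", call. = FALSE)
  }
  missing <- setdiff(assemblies$assembly_id, names(transcripts))
  if (length(missing) > 0L) {
    stop("no transcripts for assembly(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  all_ids <- unlist(lapply(transcripts, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("transcript ids must be unique across assemblies", call. = FALSE)
  }
  if (!is.null(annotations)) {
    stopifnot("transcript_id" %in% names(annotations))
    stray <- setdiff(annotations$transcript_id, all_ids)
    if (length(stray) > 0L) {
      stop("annotation keys must be a subset of transcript ids; stray: ",
           paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(assemblies = assemblies, transcripts = transcripts,
                 annotations = annotations),
            class = "assembly_catalog")
}

#' @export
print.assembly_catalog <- function(x, ...) {
  n <- vapply(x$transcripts, length, integer(1))
  cat(sprintf("assembly_catalog: %d assemblies (%s), %d transcripts\n",
              nrow(x$assemblies),
              paste(sprintf("%s:%s", x$assemblies$assembly_id,
                            x$assemblies$genus), collapse = ", "),
              sum(n)))
  invisible(x)
}
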