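#' Peptide annotation table
#'
#' Consumes externally produced per-peptide predictions (subcellular
#' localization, conserved domains, CAZy families); the package never
#' recomputes them. Domains and CAZy families are semicolon-separated in
#' the table.
#'
#' @param x data frame with columns `peptide_id`, `localization`, `domains`,
#'   `cazy_families`
#' @param localizations allowed localization vocabulary
#' @return the validated data frame
#' @export
peptide_annotations <- function(x,
                                localizations = c("extracellular",
                                                  "cytoplasmic",
                                                  "mitochondrial",
                                                  "nuclear", "membrane",
                                                  "other")) {
  need <- c("peptide_id", "localization", "domains", "cazy_families")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("annotation schema error: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !(x$localization %in% localizations)
  if (any(bad)) {
    stop("unknown localization label(s): ",
         paste(unique(x$localization[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$peptide_id)) {
    stop("duplicate peptide id(s)", call. = FALSE)
  }
  x
}

has_domain <- function(domains, domain) {
  vapply(strsplit(ifelse(is.na(domains), "", domains), ";", fixed = TRUE),
         function(d) domain %in% trimws(d), logical(1))
}

#' Call cellulosome candidates
#'
#' A peptide is a cellulosome candidate when it is predicted extracellular
#' and harbors a non-catalytic dockerin domain (a CBM_10 homolog). Pure
#' filter: the output is a subset of the input and the call is idempotent.
#'
#' @param annotations a [peptide_annotations()] table
#' @param dockerin_domain domain label marking the NCDD (default "CBM_10")
#' @return the candidate subset of the annotation table
#' @export
call_cellulosomal <- function(annotations, dockerin_domain = "CBM_10") {
  keep <- annotations$localization == "extracellular" &
    has_domain(annotations$domains, dockerin_domain)
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen peptides for scaffoldin (ScaA) homologs
#'
#' Flags a peptide when its best local alignment against any reference
#' scaffoldin reaches more than `min_identity` amino-acid identity
#' (identities / alignment length). Alignments weaker than `max_evalue`
#' are ignored so that trivially short high-identity matches do not count.
#'
#' @param peptides a [bio_seqs] collection
#' @param scaA_refs a [bio_seqs] of reference scaffoldins (non-empty)
#' @param min_identity identity floor (strict >, default 0.2734)
#' @param scheme a [scoring_scheme()]
#' @param max_evalue significance gate for the alignment (default 1e-5)
#' @return data frame: peptide_id, best_ref, identity, bit_score, flagged
#' @export
scaffoldin_screen <- function(peptides, scaA_refs, min_identity = 0.2734,
                              scheme = scoring_scheme(), max_evalue = 1e-5) {
  if (length(scaA_refs) == 0L) {
    stop("reference scaffoldin set must be non-empty", call. = FALSE)
  }
  n_db <- sum(nchar(scaA_refs))
  rows <- lapply(seq_along(peptides), function(i) {
    pid <- names(peptides)[i]
    pseq <- unclass(peptides)[[i]]
    raw <- batch_scores(pseq, unclass(scaA_refs), scheme)
    ord <- order(-raw, names(scaA_refs))
    best <- ord[1]
    al <- local_align(stats::setNames(pseq, pid),
                      stats::setNames(unclass(scaA_refs)[[best]],
                                      names(scaA_refs)[best]), scheme)
    ev <- bit_evalue(al$bit_score, nchar(pseq), n_db)
    data.frame(peptide_id = pid, best_ref = names(scaA_refs)[best],
               identity = al$identity, bit_score = al$bit_score,
               flagged = ev <= max_evalue && al$identity > min_identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CAZy family composition of cellulosome candidates
#'
#' Percentage of each CAZy family among CAZy-bearing candidates. Peptides
#' with several families are counted once per family, and percentages are
#' normalized over all (peptide, family) incidences so they sum to 100.
#'
#' @param candidates a candidate table from [call_cellulosomal()]
#' @return data frame: family, count, percent (empty for no candidates)
#' @export
cazy_composition <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(family = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  fams <- strsplit(ifelse(is.na(candidates$cazy_families), "",
                          candidates$cazy_families), ";", fixed = TRUE)
  fams <- trimws(unlist(fams))
  fams <- fams[nzchar(fams)]
  if (length(fams) == 0L) {
    return(data.frame(family = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  tab <- table(fams)
  out <- data.frame(family = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
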