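#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (ties broken
#' diagonal > up > left; the best cell is the first maximum in row-major
#' order). Returns the raw score in matrix units, its bit-score conversion,
#' identity and coverage statistics, and the aligned strings.
#'
#' @param a,b sequences: single named elements of a [bio_seqs] collection or
#'   plain strings (optionally named)
#' @param scheme a [scoring_scheme()]; its alphabet must match the sequences
#' @return an `alignment_result` list with elements `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `identity_count`, `alignment_length`,
#'   `identity` (identities / alignment length), `identity_over_shorter`
#'   (identities / length of the shorter sequence, the CD-HIT-style
#'   denominator), `aligned_query_fraction`, and the aligned strings
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  for (s in list(a, b)) {
    if (inherits(s, "bio_seqs") && attr(s, "alphabet") != scheme$alphabet) {
      stop("alphabet mismatch: scheme is ", scheme$alphabet, call. = FALSE)
    }
  }
  ida <- if (!is.null(names(a))) names(a)[1] else "query"
  idb <- if (!is.null(names(b))) names(b)[1] else "subject"
  sa <- toupper(as.character(a)[1])
  sb <- toupper(as.character(b)[1])
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty",
                                       call. = FALSE)
  res <- sw_align_cpp(sa, sb, scheme$charmap, scheme$submat,
                      scheme$gap_open, scheme$gap_extend)
  aln_len <- res$aln_len
  structure(list(
    query_id = ida, subject_id = idb,
    raw_score = res$score,
    bit_score = to_bits(res$score, scheme),
    identity_count = res$n_ident,
    alignment_length = aln_len,
    identity = if (aln_len > 0) res$n_ident / aln_len else 0,
    identity_over_shorter = res$n_ident / min(nchar(sa), nchar(sb)),
    aligned_query_fraction = (res$a_end - res$a_start + 1) / nchar(sa),
    query_range = c(res$a_start, res$a_end),
    subject_range = c(res$b_start, res$b_end),
    aligned_query = res$aln_a, aligned_subject = res$aln_b
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s vs %s: raw %d (%.1f bits), %d/%d identities (%.1f%%)\n",
              x$query_id, x$subject_id, x$raw_score, x$bit_score,
              x$identity_count, x$alignment_length, 100 * x$identity))
  invisible(x)
}

#' Batch local-alignment scores
#'
#' Score-only Smith-Waterman of one query against many subjects (vectorized
#' SIMD kernel when available; identical scores to [local_align()]).
#'
#' @param query a single sequence (string)
#' @param subjects character vector of subject sequences
#' @param scheme a [scoring_scheme()]
#' @return integer vector of raw scores, one per subject
#' @export
batch_scores <- function(query, subjects, scheme = scoring_scheme()) {
  sw_score_batch_cpp(toupper(as.character(query)[1]),
                     toupper(as.character(subjects)),
                     scheme$charmap, scheme$submat,
                     scheme$gap_open, scheme$gap_extend)
}

#' Rank similarity hits of a query against a reference database
#'
#' Every database sequence is scored with the exact local-alignment engine;
#' hits are converted to bits and E-values (`E = m*n*2^-bits` with `n` the
#' partition's residue total), filtered at `max_evalue`, sorted by bit score
#' descending with ties broken by subject id, and truncated to `top_k`.
#' Self-hits (identical id) are excluded.
#'
#' @param query single named sequence (one element of a [bio_seqs])
#' @param db a [reference_db()]
#' @param scheme a [scoring_scheme()]
#' @param top_k maximum hits returned
#' @param max_evalue E-value ceiling
#' @param details if TRUE, add identity and query-coverage columns (runs a
#'   full traceback per reported hit)
#' @return data frame with columns query_id, subject_id, partition,
#'   raw_score, bit_score, evalue (plus identity, coverage when
#'   `details = TRUE`), ranked best-first
#' @export
search_db <- function(query, db, scheme = scoring_scheme(), top_k = 100L,
                      max_evalue = 1e-3, details = FALSE) {
  stopifnot(top_k >= 1L)
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  qseq <- toupper(as.character(query)[1])
  if (length(db$sequences) == 0L) {
    hgt_log("warn", "search against empty database '%s'", db$partition)
    return(empty_hits())
  }
  subj_ids <- names(db$sequences)
  raw <- batch_scores(qseq, unclass(db$sequences), scheme)
  bits <- to_bits(raw, scheme)
  n_db <- sum(nchar(db$sequences))
  ev <- bit_evalue(bits, nchar(qseq), n_db)
  keep <- ev <= max_evalue & subj_ids != qid
  if (!any(keep)) return(empty_hits())
  hits <- data.frame(query_id = qid, subject_id = subj_ids[keep],
                     partition = db$partition, raw_score = raw[keep],
                     bit_score = bits[keep], evalue = ev[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$bit_score, hits$subject_id), , drop = FALSE]
  hits <- utils::head(hits, top_k)
  rownames(hits) <- NULL
  if (details && nrow(hits) > 0L) {
    det <- lapply(hits$subject_id, function(sid) {
      al <- local_align(stats::setNames(qseq, qid),
                        stats::setNames(unclass(db$sequences)[[sid]], sid),
                        scheme)
      c(identity = al$identity, coverage = al$aligned_query_fraction)
    })
    det <- do.call(rbind, det)
    hits$identity <- det[, "identity"]
    hits$coverage <- det[, "coverage"]
  }
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             partition = character(), raw_score = integer(),
             bit_score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Export a hit table as TSV
#'
#' Fixed column order: query, subject, partition, bits, evalue, identity,
#' coverage. Identity and coverage are computed on demand if absent.
#'
#' @param hits a hit table from [search_db()]
#' @param path output file
#' @param sequences optional named character vector to resolve sequences for
#'   identity/coverage computation when the table lacks them
#' @param scheme a [scoring_scheme()]
#' @return invisibly, `path`
#' @export
export_hits <- function(hits, path, sequences = NULL,
                        scheme = scoring_scheme()) {
  if (!all(c("identity", "coverage") %in% names(hits))) {
    if (is.null(sequences)) {
      hits$identity <- NA_real_
      hits$coverage <- NA_real_
    } else {
      det <- mapply(function(q, s) {
        al <- local_align(stats::setNames(sequences[[q]], q),
                          stats::setNames(sequences[[s]], s), scheme)
        c(al$identity, al$aligned_query_fraction)
      }, hits$query_id, hits$subject_id)
      hits$identity <- det[1, ]
      hits$coverage <- det[2, ]
    }
  }
  out <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    partition = hits$partition,
                    bits = sprintf("%.2f", hits$bit_score),
                    evalue = sprintf("%.3g", hits$evalue),
                    identity = sprintf("%.4f", hits$identity),
                    coverage = sprintf("%.4f", hits$coverage),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
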