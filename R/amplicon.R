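#' Amplicon screening policy
#'
#' The read-screening rules applied to assembled LSU D1/D2 amplicons:
#' remove sequences with ambiguous bases, homopolymer stretches longer than
#' `max_homopolymer` bases, and sequences shorter than `min_len` or longer
#' than `max_len` bp.
#'
#' @param min_len minimum length (bp), inclusive
#' @param max_len maximum length (bp), inclusive
#' @param max_homopolymer longest allowed homopolymer run
#' @param allow_ambiguous keep reads containing IUPAC ambiguity codes?
#' @return a `screen_policy` object
#' @export
screen_policy <- function(min_len = 200L, max_len = 380L,
                          max_homopolymer = 8L, allow_ambiguous = FALSE) {
  stopifnot(min_len <= max_len, max_homopolymer >= 1L)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_homopolymer = as.integer(max_homopolymer),
                 allow_ambiguous = isTRUE(allow_ambiguous)),
            class = "screen_policy")
}

#' Screen amplicon reads
#'
#' A read is rejected if it violates any rule of the policy; all violated
#' rules are recorded per read. Screening is order-independent and
#' idempotent.
#'
#' @param reads a [bio_seqs] collection (dna alphabet)
#' @param policy a [screen_policy()]
#' @return list with `kept` (a [bio_seqs]) and `rejected` (data frame with
#'   columns read_id, reasons)
#' @export
screen_reads <- function(reads, policy = screen_policy()) {
  stopifnot(attr(reads, "alphabet") == "dna")
  lens <- nchar(reads)
  homopoly <- vapply(unclass(reads), function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
  }, numeric(1))
  ambiguous <- grepl("[^ACGT]", unclass(reads))
  reasons <- mapply(function(len, hp, amb) {
    r <- character(0)
    if (len < policy$min_len) r <- c(r, "too short")
    if (len > policy$max_len) r <- c(r, "too long")
    if (hp > policy$max_homopolymer) r <- c(r, "homopolymer")
    if (amb && !policy$allow_ambiguous) r <- c(r, "ambiguous base")
    paste(r, collapse = ";")
  }, lens, homopoly, ambiguous)
  bad <- nzchar(reasons)
  list(kept = reads[!bad],
       rejected = data.frame(read_id = names(reads)[bad],
                             reasons = unname(reasons[bad]),
                             stringsAsFactors = FALSE))
}

#' Two-tier genus assignment of an amplicon read
#'
#' Tier 1 (similarity): the read is classified as its first blastn-like hit's
#' genus when the percentage similarity to that hit exceeds 96% (identities /
#' alignment length) and the two sequences align over more than 70% of the
#' query length. Tier 2 (placement): reads failing tier 1 are attached at
#' their distance-minimizing reference neighbor (Jukes-Cantor-corrected
#' distance over the local alignment); the neighbor's genus is assigned when
#' that distance is within `novelty_radius`, else the read is flagged
#' "novel-lineage". The reference tree is used to validate that references
#' are represented; placement itself is nearest-neighbor by distance.
#'
#' @param read single named sequence (dna)
#' @param refdb a [bio_seqs] of reference amplicons
#' @param ref_genus named character vector: reference id -> genus
#' @param ref_tree optional ape `phylo` whose tips are reference ids
#' @param scheme a [dna_scoring_scheme()]
#' @param min_identity tier-1 identity threshold (strict >)
#' @param min_coverage tier-1 query-coverage threshold (strict >)
#' @param novelty_radius tier-2 corrected-distance radius
#' @return one-row data frame: read_id, genus, tier, identity,
#'   query_coverage, distance
#' @export
assign_two_tier <- function(read, refdb, ref_genus, ref_tree = NULL,
                            scheme = dna_scoring_scheme(),
                            min_identity = 0.96, min_coverage = 0.70,
                            novelty_radius = 0.04) {
  if (length(refdb) == 0L) stop("empty reference database", call. = FALSE)
  if (!is.null(ref_tree) &&
      !all(ref_tree$tip.label %in% names(refdb))) {
    stop("reference tree tips must be a subset of reference db ids",
         call. = FALSE)
  }
  rid <- names(read)[1]
  rseq <- as.character(read)[1]
  raw <- batch_scores(rseq, unclass(refdb), scheme)
  ord <- order(-raw, names(refdb))
  stats <- lapply(ord, function(i) {
    al <- local_align(stats::setNames(rseq, rid),
                      stats::setNames(unclass(refdb)[[i]], names(refdb)[i]),
                      scheme)
    p <- 1 - al$identity
    d <- if (p >= 0.74) Inf else -0.75 * log(1 - 4 * p / 3)
    list(id = names(refdb)[i], identity = al$identity,
         coverage = al$aligned_query_fraction, distance = d)
  })
  first <- stats[[1]]
  if (first$identity > min_identity && first$coverage > min_coverage) {
    return(data.frame(read_id = rid, genus = unname(ref_genus[first$id]),
                      tier = "similarity", identity = first$identity,
                      query_coverage = first$coverage,
                      distance = first$distance, stringsAsFactors = FALSE))
  }
  dists <- vapply(stats, function(s) s$distance, numeric(1))
  ids <- vapply(stats, function(s) s$id, character(1))
  nn <- order(dists, ids)[1]
  genus <- if (dists[nn] <= novelty_radius) unname(ref_genus[ids[nn]]) else
    "novel-lineage"
  data.frame(read_id = rid, genus = genus, tier = "placement",
             identity = stats[[nn]]$identity,
             query_coverage = stats[[nn]]$coverage, distance = dists[nn],
             stringsAsFactors = FALSE)
}

#' Classify a set of reads
#'
#' Vectorized wrapper over [assign_two_tier()].
#'
#' @param reads a [bio_seqs] collection
#' @param ... passed to [assign_two_tier()]
#' @return data frame, one row per read
#' @export
assign_reads <- function(reads, ...) {
  rows <- lapply(seq_along(reads), function(i)
    assign_two_tier(reads[i], ...))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genus-by-sample community table
#'
#' Builds the shared-style count table from per-read genus assignments.
#' Column sums equal the number of classified reads per sample; genus rows
#' are sorted for stable output.
#'
#' @param assignments data frame with columns `sample` and `genus`
#' @return integer matrix, genera as rows, samples as columns
#' @export
community_table <- function(assignments) {
  stopifnot(all(c("sample", "genus") %in% names(assignments)))
  tab <- table(factor(assignments$genus,
                      levels = sort(unique(assignments$genus))),
               factor(assignments$sample,
                      levels = unique(assignments$sample)))
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat
}
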