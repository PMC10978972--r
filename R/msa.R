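#' Progressive multiple sequence alignment
#'
#' Internal progressive aligner used to prepare candidate hit sets for tree
#' building. A guide tree is computed by average-linkage clustering of
#' cosine distances between 3-mer count vectors; profiles are then merged
#' pairwise along the guide tree with an affine-gap profile-profile aligner
#' (free terminal gaps). Columns with more than 50% gaps are flagged via the
#' `gappy` attribute but never removed.
#'
#' @param seqs a [bio_seqs] collection (>= 1 sequence)
#' @param scheme a [scoring_scheme()] providing the substitution matrix and
#'   gap penalties
#' @param k k-mer size for the guide-tree distances
#' @return a `hgt_msa` object: named character vector of aligned sequences
#'   (input order preserved) with attributes `gappy` (logical per column)
#'   and `alphabet`
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), k = 3L) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences to align", call. = FALSE)
  ids <- names(seqs)
  enc <- lapply(unclass(seqs), function(s) {
    scheme$charmap[utf8ToInt(s) + 1L]
  })
  if (n == 1L) {
    return(new_msa(stats::setNames(as.character(seqs), ids), scheme))
  }
  # guide tree from k-mer cosine distances
  merge_order <- if (n == 2L) {
    matrix(c(-1L, -2L), 1L, 2L)
  } else {
    d <- kmer_cosine_dist(unclass(seqs), k)
    stats::hclust(stats::as.dist(d), method = "average")$merge
  }
  # each node holds an integer matrix: rows = sequences, cols = columns,
  # entries are 0-based residue codes or -1 for a gap
  leaves <- lapply(enc, function(e) matrix(e, nrow = 1L))
  leaf_ids <- as.list(ids)
  nodes <- vector("list", nrow(merge_order))
  node_ids <- vector("list", nrow(merge_order))
  fetch <- function(j) {
    if (j < 0L) list(mat = leaves[[-j]], ids = leaf_ids[[-j]])
    else list(mat = nodes[[j]], ids = node_ids[[j]])
  }
  for (r in seq_len(nrow(merge_order))) {
    a <- fetch(merge_order[r, 1L])
    b <- fetch(merge_order[r, 2L])
    res <- profile_align_cpp(a$mat, b$mat, scheme$submat + 0.0,
                             scheme$gap_open, scheme$gap_extend)
    la <- length(res$map_a)
    newa <- matrix(-1L, nrow = nrow(a$mat), ncol = la)
    sel <- res$map_a > 0L
    newa[, sel] <- a$mat[, res$map_a[sel], drop = FALSE]
    newb <- matrix(-1L, nrow = nrow(b$mat), ncol = la)
    sel <- res$map_b > 0L
    newb[, sel] <- b$mat[, res$map_b[sel], drop = FALSE]
    nodes[[r]] <- rbind(newa, newb)
    node_ids[[r]] <- c(a$ids, b$ids)
  }
  final <- nodes[[nrow(merge_order)]]
  order_ids <- unlist(node_ids[[nrow(merge_order)]])
  final <- final[match(ids, order_ids), , drop = FALSE]
  letters_m <- rownames(scheme$submat)
  aligned <- apply(final, 1L, function(row) {
    chars <- letters_m[pmax(row, 0L) + 1L]
    chars[row < 0L] <- "-"
    paste(chars, collapse = "")
  })
  new_msa(stats::setNames(aligned, ids), scheme)
}

new_msa <- function(aligned, scheme) {
  mat <- do.call(rbind, strsplit(aligned, ""))
  gappy <- colMeans(mat == "-") > 0.5
  structure(aligned, gappy = gappy, alphabet = scheme$alphabet,
            class = "hgt_msa")
}

#' @export
print.hgt_msa <- function(x, ...) {
  cat(sprintf("hgt_msa: %d sequences, %d columns (%d flagged >50%% gaps)\n",
              length(x), nchar(x[[1]]), sum(attr(x, "gappy"))))
  invisible(x)
}

kmer_cosine_dist <- function(seqs, k) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(stats::setNames(1, substr(s, 1, n)))
    kmers <- substring(s, 1:(n - k + 1), k:n)
    table(kmers)
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  norms <- vapply(counts, function(ct) sqrt(sum(as.numeric(ct)^2)), numeric(1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(counts[[i]]), names(counts[[j]]))
      dot <- sum(as.numeric(counts[[i]][shared]) *
                   as.numeric(counts[[j]][shared]))
      cosine <- dot / (norms[i] * norms[j])
      d[i, j] <- d[j, i] <- 1 - cosine
    }
  }
  d
}

#' Sum-of-pairs score of an alignment
#'
#' Mean substitution score over all aligned residue pairs per column summed
#' across columns, with affine gap costs charged per pairwise comparison.
#' Used mainly as a diagnostic for the progressive aligner.
#'
#' @param msa a `hgt_msa` object
#' @param scheme a [scoring_scheme()]
#' @return numeric sum-of-pairs score
#' @export
sum_of_pairs <- function(msa, scheme = scoring_scheme()) {
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  n <- nrow(mat)
  if (n < 2L) return(0)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + pairwise_aln_score(mat[i, ], mat[j, ], scheme)
    }
  }
  total
}

pairwise_aln_score <- function(a, b, scheme) {
  both <- a != "-" & b != "-"
  score <- sum(scheme$submat[cbind(a[both], b[both])])
  # affine gap runs in either sequence, ignoring columns gapped in both
  for (g in list(a[a != "-" | b != "-"] == "-",
                 b[a != "-" | b != "-"] == "-")) {
    r <- rle(g)
    runs <- r$lengths[r$values]
    if (length(runs) > 0L) {
      score <- score - sum(scheme$gap_open + scheme$gap_extend * runs)
    }
  }
  score
}
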