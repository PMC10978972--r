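# Independent oracles used across the suite.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# Brute-force affine-gap Smith-Waterman, written as a gap-run recurrence
# (no separate gap states): H[r, c] is the best score of a local alignment
# ending at prefix lengths (r-1, c-1), with deletions/insertions of every
# length enumerated explicitly. Independent of the package's 3-state DP.
sw_oracle <- function(a, b, submat, gap_open, gap_ext) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x)
  n <- length(y)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (r in 2:(m + 1)) {
    for (c in 2:(n + 1)) {
      s <- H[r - 1, c - 1] + submat[x[r - 1], y[c - 1]]
      del <- max(H[(r - 1):1, c] - (gap_open + gap_ext * (1:(r - 1))))
      ins <- max(H[r, (c - 1):1] - (gap_open + gap_ext * (1:(c - 1))))
      H[r, c] <- max(0, s, del, ins)
      if (H[r, c] > best) best <- H[r, c]
    }
  }
  as.integer(best)
}

# OLS branch lengths of a fixed topology for a distance matrix, and the
# residual sum of squares; used for the brute-force minimum-evolution
# topology search.
ols_fit <- function(tree, d) {
  labs <- rownames(d)
  pairs <- t(utils::combn(length(labs), 2))
  E <- nrow(tree$edge)
  X <- matrix(0, nrow(pairs), E)
  for (p in seq_len(nrow(pairs))) {
    i <- match(labs[pairs[p, 1]], tree$tip.label)
    j <- match(labs[pairs[p, 2]], tree$tip.label)
    nodes <- ape::nodepath(tree, i, j)
    for (q in seq_len(length(nodes) - 1)) {
      e <- which((tree$edge[, 1] == nodes[q] & tree$edge[, 2] == nodes[q + 1]) |
                   (tree$edge[, 2] == nodes[q] & tree$edge[, 1] == nodes[q + 1]))
      X[p, e] <- 1
    }
  }
  y <- d[cbind(labs[pairs[, 1]], labs[pairs[, 2]])]
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  rss <- sum((X %*% beta - y)^2)
  list(beta = beta, rss = rss, length = sum(beta))
}

# exhaustive minimum-evolution topology search (OLS fit per topology; the
# additive matrix's generating topology is the unique zero-residual one)
me_best_topology <- function(d) {
  labs <- rownames(d)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  best <- NULL
  best_rss <- Inf
  best_len <- Inf
  for (k in seq_along(trees)) {
    tr <- trees[[k]]  # [[ restores tip labels on a compressed multiPhylo
    fit <- ols_fit(tr, d)
    if (fit$rss < best_rss - 1e-10 ||
        (abs(fit$rss - best_rss) < 1e-10 && fit$length < best_len)) {
      best <- tr
      best_rss <- fit$rss
      best_len <- fit$length
    }
  }
  best
}

# random additive distance matrix from a random unrooted topology
random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# an MSA object directly from pre-aligned strings (bypasses the aligner)
msa_from_strings <- function(x) {
  mat <- do.call(rbind, strsplit(x, ""))
  structure(x, gappy = colMeans(mat == "-") > 0.5, alphabet = "protein",
            class = "hgt_msa")
}

# partitioned-hits record built directly (bypasses the search engine)
phit <- function(query_id = "q", ingroup = NA_real_, ...) {
  outg <- c(...)
  structure(list(query_id = query_id, best_ingroup_bits = ingroup,
                 best_outgroup_bits = outg),
            class = "partitioned_hits")
}
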