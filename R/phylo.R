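#' Pairwise distances from a protein alignment
#'
#' p-distances with Poisson correction, `d = -ln(1 - p)`, computed over
#' columns where both sequences are ungapped. Saturated pairs (p at or above
#' `p_cap`) and pairs with no overlapping columns are assigned the capped
#' distance.
#'
#' @param msa a `hgt_msa` object
#' @param p_cap proportion of differences at which the correction is capped
#' @return a symmetric distance matrix
#' @export
msa_distances <- function(msa, p_cap = 0.95) {
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  d_max <- -log(1 - p_cap)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      nn <- sum(both)
      if (nn == 0L) {
        d[i, j] <- d[j, i] <- d_max
        next
      }
      p <- sum(mat[i, both] != mat[j, both]) / nn
      d[i, j] <- d[j, i] <- if (p >= p_cap) d_max else -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds an unrooted NJ tree from Poisson-corrected p-distances and
#' estimates split supports as the fraction of `bootstrap_n` column-resampled
#' replicates containing each bipartition. Negative NJ branch lengths are
#' clamped to zero. With fewer than 4 sequences the output is degenerate
#' (star/cherry) and flagged.
#'
#' @param msa a `hgt_msa` object
#' @param bootstrap_n number of bootstrap replicates
#' @param seed RNG seed for the column resampling
#' @param tip_taxa optional data frame (id, partition, kingdom,
#'   phylum_or_class) mapping tips to lineages
#' @return a `hgt_phylogeny` object: list with elements `tree` (ape phylo),
#'   `split_support` (named frequencies, keys canonical tip-set strings),
#'   `tip_taxa`, `degenerate`
#' @export
nj_tree <- function(msa, bootstrap_n = 100L, seed = 1L, tip_taxa = NULL) {
  n <- length(msa)
  if (n < 3L) stop("need at least 3 sequences for a tree", call. = FALSE)
  degenerate <- n < 4L
  if (degenerate) {
    hgt_log("warn", "tree over %d tips is degenerate (star/cherry)", n)
  }
  d <- msa_distances(msa)
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  ncol_aln <- ncol(mat)
  boot <- vector("list", bootstrap_n)
  set.seed(seed)
  for (b in seq_len(bootstrap_n)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    sub <- mat[, cols, drop = FALSE]
    aligned <- stats::setNames(apply(sub, 1L, paste, collapse = ""),
                               names(msa))
    msab <- structure(aligned, class = "hgt_msa")
    db <- msa_distances(msab)
    tb <- ape::nj(db)
    tb$edge.length[tb$edge.length < 0] <- 0
    boot[[b]] <- tb
  }
  support <- split_frequencies(tree, boot)
  hgt_phylogeny(tree, tip_taxa = tip_taxa, split_support = support,
                degenerate = degenerate)
}

# canonical key for an unrooted bipartition: the side not containing the
# alphabetically first tip, tips sorted, joined with a separator
split_key <- function(tips, all_tips) {
  anchor <- sort(all_tips)[1]
  side <- if (anchor %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = "\x1f")
}

split_frequencies <- function(tree, boot_trees) {
  all_tips <- tree$tip.label
  counts <- new.env(parent = emptyenv())
  for (tb in boot_trees) {
    parts <- ape::prop.part(tb)
    labs <- attr(parts, "labels")
    seen <- character(0)
    for (p in parts) {
      if (length(p) <= 1L || length(p) >= length(all_tips) - 1L) next
      key <- split_key(labs[p], all_tips)
      if (!nzchar(key) || key %in% seen) next
      seen <- c(seen, key)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  B <- length(boot_trees)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(p) split_key(labs[p], all_tips), character(1))
  keep <- nzchar(keys)
  freqs <- vapply(keys[keep], function(k) {
    if (is.null(counts[[k]])) 0 else counts[[k]] / B
  }, numeric(1))
  stats::setNames(freqs, keys[keep])
}

#' Construct a phylogeny object for nesting assessment
#'
#' Wraps an ape tree with tip lineages and per-split supports. When
#' `split_support` is not given, supports are taken from the tree's node
#' labels (values above 1 are interpreted as percentages).
#'
#' @param tree an ape `phylo` object
#' @param tip_taxa data frame (id, partition, kingdom, phylum_or_class);
#'   tips without an entry are treated as lineage-less and never count
#'   toward a donor clade
#' @param split_support named numeric vector keyed by canonical split
#'   strings (internal), or NULL to derive from node labels
#' @param degenerate flag for trees too small to be informative
#' @return a `hgt_phylogeny` object
#' @export
hgt_phylogeny <- function(tree, tip_taxa = NULL, split_support = NULL,
                          degenerate = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(split_support)) {
    labs <- suppressWarnings(as.numeric(tree$node.label))
    if (length(labs) == 0L) {
      stop("tree has no node labels and no split supports were given",
           call. = FALSE)
    }
    if (any(labs > 1, na.rm = TRUE)) labs <- labs / 100
    all_tips <- tree$tip.label
    keys <- character(0)
    vals <- numeric(0)
    for (node in seq_len(tree$Nnode)) {
      tips <- clade_tip_labels(tree, ape::Ntip(tree) + node)
      keys <- c(keys, split_key(tips, all_tips))
      vals <- c(vals, labs[node])
    }
    ok <- !is.na(vals)
    split_support <- stats::setNames(vals[ok], keys[ok])
  }
  structure(list(tree = tree, tip_taxa = tip_taxa,
                 split_support = split_support, degenerate = degenerate),
            class = "hgt_phylogeny")
}

#' @export
print.hgt_phylogeny <- function(x, ...) {
  cat(sprintf("hgt_phylogeny: %d tips%s\n", ape::Ntip(x$tree),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

clade_tip_labels <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Bootstrap support of a bipartition
#'
#' Looks up the support of the split separating `tips` from the rest of the
#' tree. Trivial splits (single tip or all but one) have support 1 by
#' convention; splits never observed return 0.
#'
#' @param phy a `hgt_phylogeny`
#' @param tips character vector of tip labels on one side of the split
#' @return support in `[0, 1]`
#' @export
clade_support <- function(phy, tips) {
  all_tips <- phy$tree$tip.label
  k <- length(intersect(tips, all_tips))
  if (k <= 1L || k >= length(all_tips) - 1L) return(1)
  key <- split_key(tips, all_tips)
  if (!is.null(phy$split_support) && key %in% names(phy$split_support)) {
    unname(phy$split_support[key])
  } else {
    0
  }
}

#' Write a phylogeny to Newick
#'
#' Split supports are attached as node labels before writing, so the file
#' round-trips into an equivalent [hgt_phylogeny()].
#'
#' @param phy a `hgt_phylogeny`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_phylogeny <- function(phy, path) {
  tree <- phy$tree
  ntip <- ape::Ntip(tree)
  labs <- vapply(seq_len(tree$Nnode), function(node) {
    tips <- clade_tip_labels(tree, ntip + node)
    sprintf("%.3f", clade_support(phy, tips))
  }, character(1))
  tree$node.label <- labs
  ape::write.tree(tree, file = path)
  invisible(path)
}
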