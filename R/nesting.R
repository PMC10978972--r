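#' Assemble the per-candidate hit set for tree building
#'
#' Mirrors the two-search protocol used before tree confirmation: the top
#' `max_per_search` hits (E-value at most `max_evalue`) from a search of the
#' full database and from a search of the fungal ingroup database are pooled,
#' deduplicated by id, and combined with the query and the candidate
#' cluster's own sequences (the AGF representatives).
#'
#' @param query single named sequence (the cluster representative)
#' @param full_db_hits ranked hit table from the full (all-partition) search
#' @param ingroup_db_hits ranked hit table from the ingroup-only search
#' @param agf_refs a [bio_seqs] of AGF representative sequences (may be empty)
#' @param sequence_pool named character vector resolving subject ids
#' @param max_per_search hits taken from each search (default 100)
#' @param max_evalue E-value ceiling (default 1e-10)
#' @return a [bio_seqs] collection; attribute `reason` is set to
#'   "no homologs" when both hit lists are empty
#' @export
build_hit_set <- function(query, full_db_hits, ingroup_db_hits,
                          agf_refs = NULL, sequence_pool,
                          max_per_search = 100L, max_evalue = 1e-10) {
  qid <- names(query)[1]
  take <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0L) return(character(0))
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
    utils::head(hits$subject_id, max_per_search)
  }
  ids_full <- take(full_db_hits)
  ids_in <- take(ingroup_db_hits)
  subject_ids <- unique(c(ids_full, ids_in))
  out <- stats::setNames(as.character(query)[1], qid)
  if (!is.null(agf_refs) && length(agf_refs) > 0L) {
    extra <- setdiff(names(agf_refs), names(out))
    out <- c(out, stats::setNames(as.character(agf_refs)[match(extra, names(agf_refs))], extra))
  }
  subject_ids <- setdiff(subject_ids, names(out))
  missing <- setdiff(subject_ids, names(sequence_pool))
  if (length(missing) > 0L) {
    stop("hit subject(s) absent from sequence pool: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  out <- c(out, sequence_pool[subject_ids])
  res <- bio_seqs(out, alphabet = "protein")
  if (length(ids_full) == 0L && length(ids_in) == 0L) {
    attr(res, "reason") <- "no homologs"
  }
  res
}

#' Nesting/incongruence verdict with donor assignment
#'
#' Implements the automated reading of "nested phylogenetic affiliation
#' incongruent with organismal phylogeny with strong support": starting at
#' the query tip of the midpoint-rooted tree, ascend until the smallest
#' clade containing at least two tips outside the query's own candidate
#' cluster. The query is deemed horizontally transferred when a fraction of
#' at least `purity` of those tips shares a single non-fungal kingdom/clade
#' and the defining split has bootstrap support of at least `support_min`.
#'
#' The donor is the lowest rank shared by the donor tips: their common
#' phylum/class when unique, "Mixed phyla" with the shared kingdom when the
#' tips span several phyla of one kingdom.
#'
#' When the enclosing clade is the root (every non-cluster tip in the tree),
#' the defining split is the deepest proper clade on the query's path, i.e.
#' the bipartition separating the query group (plus any nested donor tips)
#' from the rest of the tree.
#'
#' @param phy a `hgt_phylogeny` with `tip_taxa` set
#' @param query_id the query tip label
#' @param support_min minimum bootstrap support (default 0.7)
#' @param purity minimum fraction of clade tips from a single non-fungal
#'   kingdom (default 1.0)
#' @param cluster_ids tip labels treated as the query's own group (the
#'   candidate cluster members); defaults to just the query
#' @param ingroup_kingdoms kingdom labels counting as vertical ancestry
#' @return a `placement_verdict` list: `query_id`, `is_hgt`,
#'   `defining_support`, `donor_kingdom`, `donor_phylum`,
#'   `enclosing_clade_tips`, `reason`
#' @export
assess_nesting <- function(phy, query_id, support_min = 0.7, purity = 1.0,
                           cluster_ids = query_id,
                           ingroup_kingdoms = c("Fungi",
                                                "Neocallimastigomycota")) {
  tree <- phy$tree
  if (!query_id %in% tree$tip.label) {
    stop("query '", query_id, "' is not a tip of the tree", call. = FALSE)
  }
  verdict <- function(is_hgt, support = NA_real_, kingdom = NA_character_,
                      phylum = NA_character_, tips = character(0), reason = "") {
    structure(list(query_id = query_id, is_hgt = is_hgt,
                   defining_support = support, donor_kingdom = kingdom,
                   donor_phylum = phylum, enclosing_clade_tips = tips,
                   reason = reason),
              class = "placement_verdict")
  }
  if (isTRUE(phy$degenerate) || ape::Ntip(tree) < 4L) {
    return(verdict(FALSE, reason = "degenerate tree"))
  }
  rooted <- phangorn::midpoint(tree)
  ntip <- ape::Ntip(rooted)
  parent <- integer(ntip + rooted$Nnode)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  tip_idx <- match(query_id, rooted$tip.label)
  # ascend to the smallest clade with >= 2 non-cluster tips
  node <- parent[tip_idx]
  path <- integer(0)
  enclosing <- NA_integer_
  while (node != 0L) {
    path <- c(path, node)
    tips <- clade_tip_labels(rooted, node)
    if (length(setdiff(tips, cluster_ids)) >= 2L) {
      enclosing <- node
      break
    }
    node <- if (node <= length(parent)) parent[node] else 0L
    if (is.na(node)) node <- 0L
  }
  if (is.na(enclosing)) {
    return(verdict(FALSE, reason = "no informative enclosing clade"))
  }
  clade_tips <- clade_tip_labels(rooted, enclosing)
  elig <- setdiff(clade_tips, cluster_ids)
  # lineages of the non-query tips
  taxa <- phy$tip_taxa
  kingdoms <- taxa$kingdom[match(elig, taxa$id)]
  phyla <- taxa$phylum_or_class[match(elig, taxa$id)]
  kingdoms[is.na(kingdoms)] <- "Unknown"
  tab <- sort(table(kingdoms), decreasing = TRUE)
  modal <- names(tab)[order(-tab, names(tab))][1]
  frac <- tab[[modal]] / length(elig)
  # defining split: the enclosing clade itself, or, when that clade is the
  # whole tree, the deepest proper clade on the query's path
  root_node <- ntip + 1L
  support_tips <- if (enclosing == root_node) {
    prev <- path[match(enclosing, path) - 1L]
    if (length(prev) == 0L || is.na(prev)) query_id else
      clade_tip_labels(rooted, prev)
  } else {
    clade_tips
  }
  support <- clade_support(phy, support_tips)
  if (modal %in% ingroup_kingdoms || modal == "Unknown") {
    return(verdict(FALSE, support, tips = elig,
                   reason = "congruent or uninformative placement"))
  }
  if (frac < purity) {
    return(verdict(FALSE, support, tips = elig, reason = "impure clade"))
  }
  if (support < support_min) {
    return(verdict(FALSE, support, tips = elig,
                   reason = "insufficient support"))
  }
  donor_tips <- elig[kingdoms == modal]
  donor_phyla <- unique(phyla[kingdoms == modal])
  donor_phyla <- donor_phyla[!is.na(donor_phyla) & nzchar(donor_phyla)]
  donor_phylum <- if (length(donor_phyla) == 1L) donor_phyla else
    if (length(donor_phyla) > 1L) "Mixed phyla" else NA_character_
  verdict(TRUE, support, kingdom = modal, phylum = donor_phylum,
          tips = elig, reason = "nested")
}

#' @export
print.placement_verdict <- function(x, ...) {
  if (x$is_hgt) {
    cat(sprintf("%s: HGT (support %.2f, donor %s / %s)\n", x$query_id,
                x$defining_support, x$donor_phylum, x$donor_kingdom))
  } else {
    cat(sprintf("%s: not HGT (%s)\n", x$query_id, x$reason))
  }
  invisible(x)
}
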