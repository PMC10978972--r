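#' Greedy identity clustering of sequences
#'
#' CD-HIT-style clustering: sequences are processed in length-descending
#' order (ties by id), and each sequence joins the first existing cluster
#' whose representative it matches at `threshold` identity or better, else
#' founds a new cluster. Identity uses the clustering tool's denominator:
#' identities divided by the length of the shorter sequence. The
#' representative of each cluster is its longest member (the founder).
#'
#' The result is independent of input order: the processing order is fully
#' determined by (length, id).
#'
#' @param seqs a [bio_seqs] collection
#' @param threshold identity threshold in (0, 1], default 0.95
#' @param scheme a [scoring_scheme()] for the pairwise alignments
#' @return a `hgt_clusters` object: list of clusters, each with
#'   `representative_id`, `member_ids`, and per-member identities
#' @export
greedy_cluster <- function(seqs, threshold = 0.95, scheme = scoring_scheme()) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0L) {
    return(structure(list(), threshold = threshold, class = "hgt_clusters"))
  }
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]
  ss <- unclass(seqs)[ord]
  reps <- character(0)
  clusters <- list()
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      rep_seq <- clusters[[k]]$rep_seq
      ident <- if (identical(ss[[i]], rep_seq)) {
        1
      } else {
        al <- local_align(stats::setNames(ss[[i]], ids[i]),
                          stats::setNames(rep_seq, reps[k]), scheme)
        al$identity_over_shorter
      }
      if (ident >= threshold) {
        clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, ids[i])
        clusters[[k]]$identities <- c(clusters[[k]]$identities, ident)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      clusters[[length(clusters) + 1L]] <-
        list(representative_id = ids[i], member_ids = ids[i],
             identities = 1, rep_seq = ss[[i]])
    }
  }
  structure(clusters, threshold = threshold, class = "hgt_clusters")
}

#' @export
print.hgt_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$member_ids), integer(1))
  cat(sprintf("hgt_clusters: %d cluster(s) at %.0f%% identity; sizes: %s\n",
              length(x), 100 * attr(x, "threshold"),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Flatten a clustering to a table
#'
#' @param x a `hgt_clusters` object
#' @param ... unused
#' @return data frame with columns representative, member, identity
#' @export
as.data.frame.hgt_clusters <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(representative = character(), member = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(unclass(x), function(cl) {
    data.frame(representative = cl$representative_id, member = cl$member_ids,
               identity = cl$identities, stringsAsFactors = FALSE)
  }))
}
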