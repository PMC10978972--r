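#' Split a query's hits into ingroup and outgroup best scores
#'
#' The HGT index compares the best hit in the fungal ingroup database
#' (Fungi excluding Neocallimastigomycota) with the best hit in each
#' non-fungal outgroup database. This helper reduces a combined hit table to
#' that per-partition summary.
#'
#' @param hits hit table (rows for one query, any number of partitions)
#' @param ingroup label of the ingroup partition (default "Fungi")
#' @return a `partitioned_hits` list: `query_id`, `best_ingroup_bits`
#'   (NA when the ingroup produced no hit), `best_outgroup_bits` (named
#'   numeric, one entry per outgroup partition with a hit)
#' @export
partition_hits <- function(hits, ingroup = "Fungi") {
  qid <- unique(hits$query_id)
  if (length(qid) > 1L) stop("hits for a single query expected", call. = FALSE)
  if (length(qid) == 0L) qid <- NA_character_
  ing <- hits$bit_score[hits$partition == ingroup]
  outg <- hits[hits$partition != ingroup, , drop = FALSE]
  best_out <- if (nrow(outg) > 0L) {
    v <- tapply(outg$bit_score, outg$partition, max)
    stats::setNames(as.numeric(v), names(v))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(query_id = qid,
                 best_ingroup_bits = if (length(ing) > 0L) max(ing) else NA_real_,
                 best_outgroup_bits = best_out),
            class = "partitioned_hits")
}

#' The HGT index h_U
#'
#' `h_U` is the difference between the best non-fungal (outgroup) bit score
#' and the best fungal-ingroup bit score for a query peptide; large positive
#' values indicate candidate transfers. A query with no ingroup hit
#' contributes 0 ingroup bits, so its index equals its best outgroup bit
#' score.
#'
#' @param p a [partition_hits()] result
#' @return the index value (bits)
#' @export
compute_hU <- function(p) {
  if (length(p$best_outgroup_bits) == 0L) {
    if (is.na(p$best_ingroup_bits)) {
      stop("undefined HGT index: query '", p$query_id,
           "' has no hits in any database", call. = FALSE)
    }
    stop("undefined HGT index: query '", p$query_id,
         "' has no outgroup hits", call. = FALSE)
  }
  ing <- if (is.na(p$best_ingroup_bits)) 0 else p$best_ingroup_bits
  max(p$best_outgroup_bits) - ing
}

#' Call HGT candidates by index thresholds
#'
#' A query passes when its best outgroup hit exceeds `bit_floor` bits
#' (strictly) and its HGT index is at least `hU_floor`. The bit-score test
#' applies to the single best outgroup hit, the one that defines the index.
#' Queries without any outgroup hit never pass (their index is undefined and
#' reported as NA).
#'
#' @param hits_list list of [partition_hits()] results, one per query
#' @param bit_floor outgroup bit-score floor (strict >, default 100)
#' @param hU_floor index floor (>=, default 30)
#' @return data frame with columns query_id, h_U, best_outgroup_partition,
#'   best_outgroup_bits, best_ingroup_bits, passes
#' @export
call_candidates <- function(hits_list, bit_floor = 100, hU_floor = 30) {
  stopifnot(is.finite(bit_floor), is.finite(hU_floor))
  rows <- lapply(hits_list, function(p) {
    if (length(p$best_outgroup_bits) == 0L) {
      return(data.frame(query_id = p$query_id, h_U = NA_real_,
                        best_outgroup_partition = NA_character_,
                        best_outgroup_bits = NA_real_,
                        best_ingroup_bits = p$best_ingroup_bits,
                        passes = FALSE, stringsAsFactors = FALSE))
    }
    # deterministic argmax: ties broken by partition label
    ord <- order(-p$best_outgroup_bits, names(p$best_outgroup_bits))
    best_part <- names(p$best_outgroup_bits)[ord[1]]
    best_bits <- p$best_outgroup_bits[[ord[1]]]
    hU <- compute_hU(p)
    data.frame(query_id = p$query_id, h_U = hU,
               best_outgroup_partition = best_part,
               best_outgroup_bits = best_bits,
               best_ingroup_bits = p$best_ingroup_bits,
               passes = (best_bits > bit_floor) && (hU >= hU_floor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
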