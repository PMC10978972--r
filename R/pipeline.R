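#' Run the HGT detection pipeline
#'
#' Executes the full procedure on a transcriptome catalog against
#' taxonomy-partitioned reference databases:
#' \enumerate{
#'   \item search every predicted peptide against each partition database
#'     (identical sequences are searched once);
#'   \item compute the HGT index h_U and call candidates (outgroup bit score
#'     strictly above the floor, index at or above its floor);
#'   \item cluster candidate peptides greedily at 95% identity;
#'   \item per cluster, pool the top hits of a full-database and an
#'     ingroup-only search, align them with the cluster members, build a
#'     bootstrapped NJ tree, and assess nested placement with donor
#'     assignment;
#'   \item keep confirmed clusters present in more than half of some genus's
#'     assemblies (replication filter);
#'   \item consolidate surviving clusters into distinct events and
#'     summarize.
#' }
#'
#' @param catalog an [assembly_catalog()]
#' @param refdbs named list of [reference_db()] (one per partition; must
#'   include the ingroup partition)
#' @param config configuration list from [hgt_config()]
#' @param seed seed controlling the bootstrap resampling (per-cluster seeds
#'   are derived deterministically)
#' @return a `hgt_result` list: `candidates` (index table), `clusters`,
#'   `verdicts`, `surviving` (cluster ids), `membership`, `events`,
#'   `summary`
#' @export
run_hgt_pipeline <- function(catalog, refdbs, config = hgt_config(),
                             seed = 1L) {
  scheme <- scoring_scheme(matrix = config$search$matrix,
                           gap_open = config$search$gap_open,
                           gap_extend = config$search$gap_extend,
                           lambda = config$search$lambda,
                           K = config$search$K)
  ingroup <- config$hgt_index$ingroup
  if (!ingroup %in% names(refdbs)) {
    stop("ingroup partition '", ingroup, "' not among reference databases",
         call. = FALSE)
  }
  # flatten transcripts; search unique sequences once
  tx <- do.call(rbind, lapply(names(catalog$transcripts), function(aid) {
    s <- catalog$transcripts[[aid]]
    data.frame(assembly_id = aid, transcript_id = names(s),
               seq = as.character(s), stringsAsFactors = FALSE)
  }))
  genus_of <- stats::setNames(catalog$assemblies$genus,
                              catalog$assemblies$assembly_id)
  uniq <- !duplicated(tx$seq)
  uniq_seqs <- tx$seq[uniq]
  uniq_ids <- tx$transcript_id[uniq]
  rep_of_seq <- stats::setNames(uniq_ids, uniq_seqs)
  hgt_log("info", "searching %d unique peptides (%d transcripts) against %d partitions",
          length(uniq_seqs), nrow(tx), length(refdbs))
  db_sizes <- vapply(refdbs, function(db) sum(nchar(db$sequences)),
                     numeric(1))
  hits_by_query <- vector("list", length(uniq_seqs))
  for (qi in seq_along(uniq_seqs)) {
    qseq <- uniq_seqs[qi]
    qid <- uniq_ids[qi]
    per_part <- lapply(names(refdbs), function(part) {
      db <- refdbs[[part]]
      raw <- batch_scores(qseq, unclass(db$sequences), scheme)
      bits <- to_bits(raw, scheme)
      ev <- bit_evalue(bits, nchar(qseq), db_sizes[[part]])
      keep <- ev <= config$search$max_evalue
      if (!any(keep)) return(NULL)
      data.frame(query_id = qid, subject_id = names(db$sequences)[keep],
                 partition = part, raw_score = raw[keep],
                 bit_score = bits[keep], evalue = ev[keep],
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, per_part)
    if (!is.null(hits)) {
      hits <- hits[order(-hits$bit_score, hits$subject_id), , drop = FALSE]
    } else {
      hits <- empty_hits()
    }
    hits_by_query[[qi]] <- hits
  }
  names(hits_by_query) <- uniq_ids
  # index and candidate calling per unique sequence, expanded to transcripts
  part_list <- lapply(hits_by_query, partition_hits, ingroup = ingroup)
  for (qi in seq_along(part_list))

    if (is.na(part_list[[qi]]$query_id)) part_list[[qi]]$query_id <- uniq_ids[qi]
  idx <- call_candidates(part_list, bit_floor = config$hgt_index$bit_floor,
                         hU_floor = config$hgt_index$hU_floor)
  tx$unique_rep <- rep_of_seq[tx$seq]
  idx_all <- idx[match(tx$unique_rep, idx$query_id), , drop = FALSE]
  idx_all$query_id <- tx$transcript_id
  rownames(idx_all) <- NULL
  candidates <- idx_all[idx_all$passes, , drop = FALSE]
  hgt_log("info", "%d candidate transcripts pass the index thresholds",
          nrow(candidates))
  result <- list(candidates = idx_all, clusters = NULL, verdicts = NULL,
                 surviving = character(0), membership = NULL,
                 events = empty_events(), summary = NULL)
  class(result) <- "hgt_result"
  if (nrow(candidates) == 0L) {
    result$summary <- summarize_events(result$events, NULL, catalog)
    return(result)
  }
  cand_seqs <- bio_seqs(stats::setNames(
    tx$seq[match(candidates$query_id, tx$transcript_id)],
    candidates$query_id), alphabet = "protein")
  clusters <- greedy_cluster(cand_seqs, threshold = config$cluster$threshold,
                             scheme = scheme)
  cluster_ids <- sprintf("C%03d", seq_along(clusters))
  hgt_log("info", "%d candidate cluster(s)", length(clusters))
  # sequence pool for hit-set building
  pool <- unlist(lapply(refdbs, function(db)
    stats::setNames(as.character(db$sequences), names(db$sequences))))
  names(pool) <- unlist(lapply(refdbs, function(db) names(db$sequences)))
  taxonomy <- do.call(rbind, lapply(refdbs, function(db) db$taxonomy))
  agf_taxa <- data.frame(id = names(cand_seqs), partition = "AGF",
                         kingdom = "Neocallimastigomycota",
                         phylum_or_class = "Neocallimastigomycota",
                         stringsAsFactors = FALSE)
  tip_taxa <- rbind(taxonomy, agf_taxa)
  verdicts <- vector("list", length(clusters))
  membership_rows <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    rep_id <- cl$representative_id
    rep_hits <- hits_by_query[[tx$unique_rep[match(rep_id,
                                                   tx$transcript_id)]]]
    rep_hits$query_id <- rep_id
    # full-database ranking: joint E-values over the combined search space
    full_hits <- rep_hits
    if (nrow(full_hits) > 0L) {
      full_hits$evalue <- bit_evalue(full_hits$bit_score,
                                     nchar(cl$rep_seq), sum(db_sizes))
      full_hits <- full_hits[order(-full_hits$bit_score,
                                   full_hits$subject_id), , drop = FALSE]
    }
    ingroup_hits <- rep_hits[rep_hits$partition == ingroup, , drop = FALSE]
    members <- cand_seqs[cl$member_ids]
    hit_set <- build_hit_set(
      stats::setNames(cl$rep_seq, rep_id), full_hits, ingroup_hits,
      agf_refs = members[setdiff(names(members), rep_id)],
      sequence_pool = pool,
      max_per_search = config$phylo$max_per_search,
      max_evalue = config$phylo$max_evalue)
    verdicts[[k]] <- if (!is.null(attr(hit_set, "reason")) ||
                         length(hit_set) < 4L) {
      structure(list(query_id = rep_id, is_hgt = FALSE,
                     defining_support = NA_real_,
                     donor_kingdom = NA_character_,
                     donor_phylum = NA_character_,
                     enclosing_clade_tips = character(0),
                     reason = if (!is.null(attr(hit_set, "reason")))
                       attr(hit_set, "reason") else "degenerate tree"),
                class = "placement_verdict")
    } else {
      msa <- progressive_align(hit_set, scheme)
      phy <- nj_tree(msa, bootstrap_n = config$phylo$bootstrap_n,
                     seed = seed + k,
                     tip_taxa = tip_taxa)
      assess_nesting(phy, rep_id,
                     support_min = config$phylo$support_min,
                     purity = config$phylo$purity,
                     cluster_ids = cl$member_ids)
    }
    membership_rows[[k]] <- data.frame(
      cluster_id = cluster_ids[k], transcript_id = cl$member_ids,
      assembly_id = tx$assembly_id[match(cl$member_ids, tx$transcript_id)],
      stringsAsFactors = FALSE)
  }
  membership <- do.call(rbind, membership_rows)
  membership$genus <- unname(genus_of[membership$assembly_id])
  confirmed <- vapply(verdicts, function(v) v$is_hgt, logical(1))
  hgt_log("info", "%d cluster(s) confirmed by the nesting test",
          sum(confirmed))
  cluster_assemblies <- lapply(split(membership$assembly_id,
                                     membership$cluster_id), unique)
  surviving <- replication_filter(
    cluster_assemblies[cluster_ids[confirmed]],
    catalog$assemblies, min_prevalence = config$events$min_prevalence)
  hgt_log("info", "%d cluster(s) survive the replication filter",
          length(surviving))
  ann <- catalog$annotations
  keep <- match(surviving, cluster_ids)
  cluster_table <- do.call(rbind, lapply(keep, function(k) {
    cl <- clusters[[k]]
    v <- verdicts[[k]]
    a <- if (!is.null(ann)) {
      ann[match(cl$representative_id, ann$transcript_id), , drop = FALSE]
    } else {
      NULL
    }
    data.frame(
      cluster_id = cluster_ids[k],
      representative_id = cl$representative_id,
      function_label = if (!is.null(a)) a$function_label else NA_character_,
      cog_class = if (!is.null(a) && "cog_class" %in% names(ann))
        a$cog_class else NA_character_,
      cazy_family = if (!is.null(a) && "cazy_family" %in% names(ann))
        a$cazy_family else NA_character_,
      donor_kingdom = v$donor_kingdom, donor_phylum = v$donor_phylum,
      stringsAsFactors = FALSE)
  }))
  verdict_table <- do.call(rbind, lapply(seq_along(verdicts), function(k) {
    v <- verdicts[[k]]
    data.frame(cluster_id = cluster_ids[k], query_id = v$query_id,
               is_hgt = v$is_hgt, support = v$defining_support,
               donor_kingdom = v$donor_kingdom,
               donor_phylum = v$donor_phylum, reason = v$reason,
               stringsAsFactors = FALSE)
  }))
  result$clusters <- clusters
  result$cluster_ids <- cluster_ids
  result$verdicts <- verdict_table
  result$surviving <- surviving
  result$membership <- membership
  if (!is.null(cluster_table) && nrow(cluster_table) > 0L) {
    rep_seq_pool <- stats::setNames(
      vapply(clusters[keep], function(cl) cl$rep_seq, character(1)),
      cluster_table$representative_id)
    result$events <- consolidate_events(
      cluster_table,
      membership[membership$cluster_id %in% surviving, , drop = FALSE],
      rep_seqs = rep_seq_pool,
      rep_identity = config$cluster$threshold, scheme = scheme)
  }
  result$summary <- summarize_events(result$events, result$membership,
                                     catalog)
  result
}

#' @export
print.hgt_result <- function(x, ...) {
  cat(sprintf("hgt_result: %d candidates, %d events\n",
              sum(x$candidates$passes, na.rm = TRUE), nrow(x$events)))
  print(x$summary)
  invisible(x)
}

#' Write pipeline stage outputs
#'
#' Emits the candidate index table, cluster table, verdict table, event
#' table and per-assembly summary as deterministic TSVs.
#'
#' @param result a `hgt_result`
#' @param dir output directory
#' @return invisibly, the files written
#' @export
write_hgt_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "candidates.tsv")
  cand <- result$candidates
  num <- vapply(cand, is.numeric, logical(1))
  cand[num] <- lapply(cand[num], function(v) sprintf("%.4f", v))
  write_tsv(cand, f)
  files <- c(files, f)
  if (!is.null(result$membership)) {
    f <- file.path(dir, "clusters.tsv")
    write_tsv(result$membership, f)
    files <- c(files, f)
  }
  if (!is.null(result$verdicts)) {
    f <- file.path(dir, "verdicts.tsv")
    v <- result$verdicts
    v$support <- sprintf("%.3f", v$support)
    write_tsv(v, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "events.tsv")
  write_tsv(render_event_table(result$events), f)
  files <- c(files, f)
  if (!is.null(result$summary$per_assembly)) {
    f <- file.path(dir, "summary_per_assembly.tsv")
    s <- result$summary$per_assembly
    s$pct_transcripts <- sprintf("%.4f", s$pct_transcripts)
    s$pct_cazyome <- sprintf("%.4f", s$pct_cazyome)
    write_tsv(s, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Score pipeline output against the simulator truth table
#'
#' Matches reported events to planted gene families through their function
#' labels (one label per simulated family) and computes precision, recall,
#' and donor-kingdom accuracy among events that correspond to planted
#' transfers.
#'
#' @param result a `hgt_result` from [run_hgt_pipeline()]
#' @param truth the truth table from [simulate_hgt_data()]
#' @return list: n_events, n_planted, true_positives, precision, recall,
#'   donor_kingdom_accuracy
#' @export
evaluate_against_truth <- function(result, truth) {
  events <- result$events
  planted <- truth[truth$is_transfer, , drop = FALSE]
  n_events <- nrow(events)
  if (n_events == 0L) {
    return(list(n_events = 0L, n_planted = nrow(planted),
                true_positives = 0L, precision = NA_real_, recall = 0,
                donor_kingdom_accuracy = NA_real_))
  }
  idx <- match(events$function_label, truth$function_label)
  is_tp <- !is.na(idx) & truth$is_transfer[idx]
  recalled <- unique(events$function_label[is_tp])
  donor_ok <- events$donor_kingdom[is_tp] == truth$donor_kingdom[idx[is_tp]]
  list(n_events = n_events, n_planted = nrow(planted),
       true_positives = sum(is_tp),
       precision = sum(is_tp) / n_events,
       recall = if (nrow(planted) > 0L)
         length(recalled) / nrow(planted) else NA_real_,
       donor_kingdom_accuracy = if (sum(is_tp) > 0L)
         mean(donor_ok) else NA_real_)
}
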