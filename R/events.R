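#' Normalize a function label
#'
#' Case-folds, strips parenthetical gene symbols, and collapses whitespace,
#' so catalog matching is robust to formatting differences.
#'
#' @param x character vector of function labels
#' @return normalized labels
#' @export
norm_function_label <- function(x) {
  x <- tolower(x)
  x <- gsub("\\([^)]*\\)", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Per-genus replication filter
#'
#' The contamination safeguard: a candidate cluster is kept only when, in at
#' least one genus, it occurs in strictly more than `min_prevalence` of that
#' genus's transcriptomic assemblies. With the study design (n = 5 and
#' n = 2 assemblies), 3/5 survives (0.6 > 0.5) while 1/2 does not.
#'
#' @param cluster_assemblies named list: cluster id -> character vector of
#'   assembly ids in which the cluster has a member
#' @param assemblies data frame with columns `assembly_id`, `genus`
#' @param min_prevalence prevalence floor (strict >, default 0.5)
#' @return character vector of surviving cluster ids
#' @export
replication_filter <- function(cluster_assemblies, assemblies,
                               min_prevalence = 0.5) {
  genus_n <- table(assemblies$genus)
  if (any(genus_n == 0L) || nrow(assemblies) == 0L) {
    stop("every genus must have at least one assembly", call. = FALSE)
  }
  genus_of <- stats::setNames(assemblies$genus, assemblies$assembly_id)
  survives <- vapply(cluster_assemblies, function(asm) {
    asm <- unique(asm)
    unknown <- setdiff(asm, names(genus_of))
    if (length(unknown) > 0L) {
      stop("assembly not in catalog: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    counts <- table(factor(genus_of[asm], levels = names(genus_n)))
    any(counts / as.vector(genus_n) > min_prevalence)
  }, logical(1))
  names(cluster_assemblies)[survives]
}

#' Consolidate confirmed clusters into distinct HGT events
#'
#' Clusters merge into one event when their normalized function label and
#' donor phylum/class agree. Because the same function can be acquired more
#' than once, an additional rule keeps clusters apart when their
#' representative sequences share less than `rep_identity` identity (the
#' clustering threshold); within a (function, donor) group, single-linkage
#' components at that identity become separate events. Clusters lacking a
#' function annotation are reported as "uncharacterized protein".
#'
#' @param clusters data frame with one row per confirmed cluster: columns
#'   `cluster_id`, `representative_id`, `function_label`, `cog_class`,
#'   `donor_kingdom`, `donor_phylum`, optional `cazy_family`
#' @param membership data frame with columns `cluster_id`, `transcript_id`,
#'   `assembly_id`, `genus`
#' @param rep_seqs optional named character vector of representative
#'   sequences (enables the identity sub-split)
#' @param rep_identity identity floor for merging same-function events
#' @param scheme a [scoring_scheme()]
#' @return data frame of events: `event_id`, `function_label`, `cog_class`,
#'   `donor_kingdom`, `donor_phylum`, `genus_distribution`, `is_cazyme`,
#'   `cazy_family`, `n_transcripts`, `cluster_ids`
#' @export
consolidate_events <- function(clusters, membership, rep_seqs = NULL,
                               rep_identity = 0.95,
                               scheme = scoring_scheme()) {
  if (nrow(clusters) == 0L) return(empty_events())
  clusters$function_label[is.na(clusters$function_label) |
                            !nzchar(clusters$function_label)] <-
    "uncharacterized protein"
  if (!"cog_class" %in% names(clusters)) clusters$cog_class <- NA_character_
  if (!"cazy_family" %in% names(clusters)) {
    clusters$cazy_family <- cazy_family_of(clusters$function_label)
  }
  norm <- norm_function_label(clusters$function_label)
  donor_key <- ifelse(is.na(clusters$donor_phylum) |
                        !nzchar(clusters$donor_phylum),
                      paste0("kingdom:", clusters$donor_kingdom),
                      clusters$donor_phylum)
  key <- paste(norm, donor_key, sep = "\x1f")
  groups <- split(seq_len(nrow(clusters)), key)
  events <- list()
  for (g in groups) {
    comps <- if (length(g) > 1L && !is.null(rep_seqs)) {
      identity_components(clusters$representative_id[g], rep_seqs,
                          rep_identity, scheme)
    } else {
      rep.int(1L, length(g))
    }
    for (comp in sort(unique(comps))) {
      events[[length(events) + 1L]] <- g[comps == comp]
    }
  }
  # deterministic event order: by function label then donor
  first_idx <- vapply(events, function(g) g[1], integer(1))
  ord <- order(norm[first_idx], donor_key[first_idx])
  events <- events[ord]
  rows <- lapply(seq_along(events), function(e) {
    g <- events[[e]]
    cl_ids <- clusters$cluster_id[g]
    mem <- membership[membership$cluster_id %in% cl_ids, , drop = FALSE]
    genera <- sort(unique(mem$genus))
    dist_label <- if (length(genera) == 1L) genera else "Both"
    caz <- unique(clusters$cazy_family[g])
    caz <- caz[!is.na(caz) & nzchar(caz)]
    data.frame(
      event_id = NA_character_,
      function_label = clusters$function_label[g[1]],
      cog_class = clusters$cog_class[g[1]],
      donor_kingdom = clusters$donor_kingdom[g[1]],
      donor_phylum = clusters$donor_phylum[g[1]],
      genus_distribution = dist_label,
      is_cazyme = length(caz) > 0L,
      cazy_family = if (length(caz) > 0L) paste(caz, collapse = ";") else
        NA_character_,
      n_transcripts = nrow(mem),
      cluster_ids = paste(cl_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$event_id <- sprintf("E%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(event_id = character(), function_label = character(),
             cog_class = character(), donor_kingdom = character(),
             donor_phylum = character(), genus_distribution = character(),
             is_cazyme = logical(), cazy_family = character(),
             n_transcripts = integer(), cluster_ids = character(),
             stringsAsFactors = FALSE)
}

# single-linkage components among representatives at >= threshold identity
identity_components <- function(rep_ids, rep_seqs, threshold, scheme) {
  n <- length(rep_ids)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- rep_seqs[[rep_ids[i]]]
      b <- rep_seqs[[rep_ids[j]]]
      if (is.null(a) || is.null(b)) next
      ident <- if (identical(a, b)) 1 else {
        local_align(stats::setNames(a, rep_ids[i]),
                    stats::setNames(b, rep_ids[j]), scheme)$identity_over_shorter
      }
      if (ident >= threshold) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  match(comp, unique(comp))
}

#' CAZy family from a function label
#'
#' Recognizes glycoside hydrolase (GH), carbohydrate esterase (CE) and
#' polysaccharide lyase (PL) family labels such as "GH13" or "CE1".
#'
#' @param x character vector of function labels
#' @return the CAZy family label, or NA when the label is not a CAZy family
#' @export
cazy_family_of <- function(x) {
  m <- regmatches(x, regexpr("^(GH|CE|PL)[0-9]+$", toupper(trimws(x))))
  out <- rep(NA_character_, length(x))
  out[toupper(trimws(x)) %in% m] <- toupper(trimws(x))[toupper(trimws(x)) %in% m]
  out
}

#' Compare events with a reference event catalog
#'
#' Sets `in_reference_catalog` by normalized-function match and `same_donor`
#' by donor phylum/class (and kingdom) equality; `same_donor` is "N/A" for
#' events absent from the catalog.
#'
#' @param events an event table from [consolidate_events()] or
#'   [read_event_table()]
#' @param catalog data frame with columns `function_label`, `donor_phylum`,
#'   `donor_kingdom`
#' @return the event table with columns `in_reference_catalog` (logical) and
#'   `same_donor` ("Yes"/"No"/"N/A") set
#' @export
compare_catalog <- function(events, catalog) {
  if (nrow(events) == 0L) return(events)
  cat_norm <- norm_function_label(catalog$function_label)
  ev_norm <- norm_function_label(events$function_label)
  idx <- match(ev_norm, cat_norm)
  events$in_reference_catalog <- !is.na(idx)
  same <- rep("N/A", nrow(events))
  hit <- which(!is.na(idx))
  eq <- function(a, b) {
    a[is.na(a)] <- ""
    b[is.na(b)] <- ""
    a == b
  }
  same[hit] <- ifelse(
    eq(events$donor_phylum[hit], catalog$donor_phylum[idx[hit]]) &
      eq(events$donor_kingdom[hit], catalog$donor_kingdom[idx[hit]]),
    "Yes", "No")
  events$same_donor <- same
  events
}

#' Summarize an event catalog against the transcriptome catalog
#'
#' Computes, per assembly, the percentage of transcripts assigned to HGT
#' events and the percentage of the CAZyome (CAZy-annotated transcripts)
#' assigned to CAZy HGT events, reporting mean and sample (n-1) standard
#' deviation across assemblies, plus event counts by donor kingdom and
#' COG/KEGG class.
#'
#' @param events event table
#' @param membership data frame (`cluster_id`, `transcript_id`,
#'   `assembly_id`, `genus`) for the clusters behind the events; NULL for
#'   fixture-only catalogs (percentages are then skipped)
#' @param catalog an [assembly_catalog()]; NULL for fixture-only catalogs
#' @return a `hgt_summary` list
#' @export
summarize_events <- function(events, membership = NULL, catalog = NULL) {
  n_events <- nrow(events)
  n_cazy <- sum(events$is_cazyme)
  by_kingdom <- if (n_events > 0L) table(events$donor_kingdom) else table(character())
  by_class <- if (n_events > 0L) table(events$cog_class) else table(character())
  out <- list(n_events = n_events, n_cazy_events = n_cazy,
              events_by_donor_kingdom = by_kingdom,
              events_by_class = by_class,
              pct_transcripts = NULL, pct_cazyome = NULL)
  if (!is.null(membership) && !is.null(catalog)) {
    event_clusters <- strsplit(events$cluster_ids, ";", fixed = TRUE)
    hgt_tx <- membership$transcript_id[membership$cluster_id %in%
                                         unlist(event_clusters)]
    cazy_clusters <- unlist(event_clusters[events$is_cazyme])
    cazy_hgt_tx <- membership$transcript_id[membership$cluster_id %in%
                                              cazy_clusters]
    ann <- catalog$annotations
    cazy_tx <- if (!is.null(ann) && "cazy_family" %in% names(ann)) {
      ann$transcript_id[!is.na(ann$cazy_family) & nzchar(ann$cazy_family)]
    } else {
      character(0)
    }
    per_assembly <- lapply(catalog$assemblies$assembly_id, function(a) {
      tx <- names(catalog$transcripts[[a]])
      if (length(tx) == 0L) {
        hgt_log("warn", "assembly %s has no transcripts; excluded", a)
        return(NULL)
      }
      caz <- intersect(tx, cazy_tx)
      data.frame(
        assembly_id = a,
        n_transcripts = length(tx),
        pct_transcripts = 100 * length(intersect(tx, hgt_tx)) / length(tx),
        n_cazy = length(caz),
        pct_cazyome = if (length(caz) > 0L)
          100 * length(intersect(caz, cazy_hgt_tx)) / length(caz) else NA_real_,
        stringsAsFactors = FALSE)
    })
    per_assembly <- do.call(rbind, per_assembly)
    out$per_assembly <- per_assembly
    out$pct_transcripts <- c(
      mean = mean(per_assembly$pct_transcripts),
      sd = stats::sd(per_assembly$pct_transcripts))
    pc <- per_assembly$pct_cazyome[!is.na(per_assembly$pct_cazyome)]
    out$pct_cazyome <- c(mean = mean(pc), sd = stats::sd(pc))
  }
  structure(out, class = "hgt_summary")
}

#' @export
print.hgt_summary <- function(x, ...) {
  cat(sprintf("HGT events: %d distinct (%d CAZy)\n", x$n_events,
              x$n_cazy_events))
  if (!is.null(x$pct_transcripts)) {
    cat(sprintf("  %% transcripts in HGT events: %.2f +/- %.2f\n",
                x$pct_transcripts[["mean"]], x$pct_transcripts[["sd"]]))
  }
  if (!is.null(x$pct_cazyome) && !is.na(x$pct_cazyome[["mean"]])) {
    cat(sprintf("  %% CAZyome in CAZy HGT events: %.2f +/- %.2f\n",
                x$pct_cazyome[["mean"]], x$pct_cazyome[["sd"]]))
  }
  if (length(x$events_by_donor_kingdom) > 0L) {
    cat("  by donor kingdom:",
        paste(sprintf("%s=%d", names(x$events_by_donor_kingdom),
                      as.integer(x$events_by_donor_kingdom)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Render an event table to TSV
#'
#' Rows are grouped by COG/KEGG class and ordered deterministically
#' (class, function label, donor, distribution), so the same set of events
#' always produces byte-identical output regardless of input order.
#'
#' @param events event table (after [compare_catalog()] if occurrence flags
#'   are wanted)
#' @param path output file, or NULL to return the data frame
#' @return the rendered data frame (invisibly when `path` is given)
#' @export
render_event_table <- function(events, path = NULL) {
  yn <- function(x) ifelse(is.na(x), "N/A", ifelse(x, "Yes", "No"))
  occurrence <- if ("in_reference_catalog" %in% names(events)) {
    yn(events$in_reference_catalog)
  } else {
    rep("N/A", nrow(events))
  }
  same <- if ("same_donor" %in% names(events)) events$same_donor else
    rep("N/A", nrow(events))
  blank <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(
    cog_class = blank(events$cog_class),
    function_label = events$function_label,
    donor_phylum = blank(events$donor_phylum),
    donor_kingdom = blank(events$donor_kingdom),
    distribution = events$genus_distribution,
    occurrence_in_reference = occurrence,
    same_donor = same,
    stringsAsFactors = FALSE)
  ord <- order(out$cog_class, norm_function_label(out$function_label),
               out$donor_phylum, out$distribution)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write_tsv(out, path)
    return(invisible(out))
  }
  out
}

#' Read a machine-readable event table
#'
#' Loads a TSV event catalog (such as the packaged tortoise HGT event
#' fixture) into the event-table schema used throughout the package.
#'
#' @param path TSV with columns `cog_class`, `function_label`,
#'   `donor_phylum`, `donor_kingdom`, `distribution`,
#'   `occurrence_in_reference`, `same_donor`
#' @return an event table
#' @export
read_event_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("cog_class", "function_label", "donor_phylum", "donor_kingdom",
            "distribution")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("event table schema error: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  caz <- cazy_family_of(tab$function_label)
  ev <- data.frame(
    event_id = sprintf("E%03d", seq_len(nrow(tab))),
    function_label = tab$function_label,
    cog_class = tab$cog_class,
    donor_kingdom = ifelse(nzchar(tab$donor_kingdom), tab$donor_kingdom,
                           NA_character_),
    donor_phylum = ifelse(nzchar(tab$donor_phylum), tab$donor_phylum,
                          NA_character_),
    genus_distribution = tab$distribution,
    is_cazyme = !is.na(caz),
    cazy_family = caz,
    n_transcripts = NA_integer_,
    cluster_ids = NA_character_,
    stringsAsFactors = FALSE)
  if ("occurrence_in_reference" %in% names(tab)) {
    ev$in_reference_catalog <- tab$occurrence_in_reference == "Yes"
    ev$same_donor <- tab$same_donor
  }
  ev
}
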