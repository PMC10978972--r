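study_assemblies <- function() {
  data.frame(assembly_id = c(paste0("T", 1:5), paste0("B", 1:2)),
             genus = c(rep("T", 5), rep("B", 2)), stringsAsFactors = FALSE)
}

test_that("replication filter enforces the strict >50% per-genus rule", {
  asm <- study_assemblies()
  survivors <- replication_filter(list(
    in3of5 = c("T1", "T2", "T3"),          # 0.6 > 0.5: survives
    in2of5 = c("T1", "T2"),                # 0.4: dropped
    in1of2 = "B1",                         # 0.5 is not > 0.5: dropped
    in2of2 = c("B1", "B2"),                # 1.0: survives
    nowhere = character(0),                # dropped
    spread = c("T1", "B1", "B2")           # survives through genus B
  ), asm)
  expect_setequal(survivors, c("in3of5", "in2of2", "spread"))
  expect_error(replication_filter(list(x = "Z9"), asm), "not in catalog")
  expect_error(replication_filter(list(), asm[0, ]), "at least one assembly")
})

test_that("lowering the prevalence floor never removes a survivor", {
  asm <- study_assemblies()
  set.seed(61)
  for (r in 1:30) {
    clusters <- lapply(1:6, function(i)
      sample(asm$assembly_id, sample(0:7, 1)))
    names(clusters) <- paste0("c", 1:6)
    hi <- replication_filter(clusters, asm, min_prevalence = 0.5)
    lo <- replication_filter(clusters, asm, min_prevalence = 0.3)
    expect_true(all(hi %in% lo))
  }
})

test_that("events merge on function and donor, split on distinct sequences", {
  membership <- data.frame(
    cluster_id = c("c1", "c1", "c2", "c3"),
    transcript_id = c("t1", "t2", "t3", "t4"),
    assembly_id = c("T1", "T2", "B1", "T3"),
    genus = c("T", "T", "B", "T"), stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster_id = c("c1", "c2", "c3"),
    representative_id = c("t1", "t3", "t4"),
    function_label = c("GH13", "GH13", "GH13"),
    cog_class = "[G] Carbohydrate transport and metabolism",
    donor_kingdom = c("Bacteria", "Bacteria", "Bacteria"),
    donor_phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
    stringsAsFactors = FALSE)
  set.seed(63)
  shared <- random_protein(60)
  reps <- c(t1 = shared, t3 = shared, t4 = random_protein(60))
  ev <- consolidate_events(clusters, membership, rep_seqs = reps)
  # same function + same donor + same sequence merge (distribution Both);
  # a different donor phylum stays separate
  expect_equal(nrow(ev), 2L)
  merged <- ev[ev$donor_phylum == "Firmicutes", ]
  expect_equal(merged$genus_distribution, "Both")
  expect_equal(merged$n_transcripts, 3L)
  expect_true(all(ev$is_cazyme))
  # same key but dissimilar representatives stay distinct events
  reps_far <- c(t1 = shared, t3 = shared, t4 = random_protein(60))
  clusters2 <- clusters
  clusters2$donor_phylum <- "Firmicutes"
  ev2 <- consolidate_events(clusters2, membership, rep_seqs = reps_far)
  expect_equal(nrow(ev2), 2L)
  # a cluster without a function annotation becomes "uncharacterized protein"
  clusters3 <- clusters[1, ]
  clusters3$function_label <- NA_character_
  ev3 <- consolidate_events(clusters3, membership[1:2, ])
  expect_equal(ev3$function_label, "uncharacterized protein")
  # empty input
  expect_equal(nrow(consolidate_events(clusters[0, ], membership[0, ])), 0L)
})

test_that("event transcripts are conserved through consolidation", {
  set.seed(67)
  n_cl <- 5L
  membership <- data.frame(
    cluster_id = rep(paste0("c", 1:n_cl), each = 3),
    transcript_id = paste0("t", 1:(3 * n_cl)),
    assembly_id = sample(study_assemblies()$assembly_id, 3 * n_cl, TRUE),
    stringsAsFactors = FALSE)
  membership$genus <- substr(membership$assembly_id, 1, 1)
  clusters <- data.frame(
    cluster_id = paste0("c", 1:n_cl),
    representative_id = paste0("t", seq(1, 3 * n_cl, by = 3)),
    function_label = c("fnA", "fnA", "fnB", "fnC", "fnC"),
    cog_class = NA_character_,
    donor_kingdom = "Bacteria",
    donor_phylum = c("Firmicutes", "Firmicutes", "Firmicutes",
                     "Bacteroidetes", "Proteobacteria"),
    stringsAsFactors = FALSE)
  ev <- consolidate_events(clusters, membership)
  expect_equal(sum(ev$n_transcripts), nrow(membership))
})

test_that("catalog comparison flags occurrence and donor agreement", {
  catalog <- data.frame(
    function_label = c("Cysteine synthase", "guanine deaminase"),
    donor_phylum = c("Actinobacteria", "Firmicutes"),
    donor_kingdom = c("Bacteria", "Bacteria"), stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("E001", "E002", "E003"),
    function_label = c("Cysteine synthase", "guanine deaminase",
                       "thymidine kinase"),
    cog_class = NA_character_,
    donor_kingdom = "Bacteria",
    donor_phylum = c("Firmicutes", "Firmicutes", "Alpha-Proteobacteria"),
    genus_distribution = "Both", is_cazyme = FALSE,
    cazy_family = NA_character_, n_transcripts = 1L, cluster_ids = "c",
    stringsAsFactors = FALSE)
  out <- compare_catalog(events, catalog)
  # same function, different catalog donor
  expect_true(out$in_reference_catalog[1])
  expect_equal(out$same_donor[1], "No")
  # same function, same donor
  expect_equal(out$same_donor[2], "Yes")
  # absent from the catalog
  expect_false(out$in_reference_catalog[3])
  expect_equal(out$same_donor[3], "N/A")
  # empty catalog: everything (false, N/A)
  out2 <- compare_catalog(events, catalog[0, ])
  expect_true(all(!out2$in_reference_catalog))
  expect_true(all(out2$same_donor == "N/A"))
})

test_that("summaries compute per-assembly percentages with sample sd", {
  seqs <- function(ids) bio_seqs(stats::setNames(
    vapply(seq_along(ids), function(i) random_protein(20), ""), ids))
  set.seed(71)
  catalog <- assembly_catalog(
    data.frame(assembly_id = c("A1", "A2"), genus = c("T", "B"),
               stringsAsFactors = FALSE),
    list(A1 = seqs(sprintf("A1_t%02d", 1:10)),
         A2 = seqs(sprintf("A2_t%02d", 1:5))),
    annotations = data.frame(
      transcript_id = c("A1_t01", "A1_t02", "A2_t01"),
      function_label = "fnA", cog_class = "[G]",
      cazy_family = c("GH5", NA, "GH5"), stringsAsFactors = FALSE))
  membership <- data.frame(
    cluster_id = "c1", transcript_id = c("A1_t01", "A2_t01"),
    assembly_id = c("A1", "A2"), genus = c("T", "B"),
    stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = "E001", function_label = "fnA", cog_class = "[G]",
    donor_kingdom = "Bacteria", donor_phylum = "Firmicutes",
    genus_distribution = "Both", is_cazyme = TRUE, cazy_family = "GH5",
    n_transcripts = 2L, cluster_ids = "c1", stringsAsFactors = FALSE)
  s <- summarize_events(events, membership, catalog)
  # 1/10 and 1/5 transcripts in events
  expect_equal(unname(s$per_assembly$pct_transcripts), c(10, 20))
  expect_equal(s$pct_transcripts[["mean"]], 15)
  expect_equal(s$pct_transcripts[["sd"]], stats::sd(c(10, 20)))
  # CAZyome: A1 has 1 CAZy transcript (in the event), A2 has 1 (in it too)
  expect_equal(s$pct_cazyome[["mean"]], 100)
  expect_equal(s$n_cazy_events, 1L)
  # no events: zero counts
  s0 <- summarize_events(empty_ev <- events[0, ], membership[0, ], catalog)
  expect_equal(s0$n_events, 0L)
})

test_that("the packaged event fixture reproduces the published tallies", {
  f <- system.file("extdata", "tortoise_hgt_events.tsv",
                   package = "hgtsieve")
  events <- read_event_table(f)
  expect_equal(nrow(events), 35L)
  expect_equal(sum(events$is_cazyme), 13L)
  s <- summarize_events(events)
  expect_equal(s$n_events, 35L)
  expect_equal(s$n_cazy_events, 13L)
  # donor kingdoms as printed
  expect_equal(unname(s$events_by_donor_kingdom[["Bacteria"]]), 31L)
  expect_equal(unname(s$events_by_donor_kingdom[["Metazoa"]]), 2L)
})

test_that("fixture flags are reproduced by comparison with the synthetic catalog", {
  events <- read_event_table(system.file("extdata",
                                         "tortoise_hgt_events.tsv",
                                         package = "hgtsieve"))
  catalog <- read_tsv(system.file("extdata",
                                  "magf_event_catalog_synthetic.tsv",
                                  package = "hgtsieve"))
  printed_occurrence <- events$in_reference_catalog
  printed_same <- events$same_donor
  recomputed <- compare_catalog(events[setdiff(names(events),
                                               c("in_reference_catalog",
                                                 "same_donor"))], catalog)
  expect_equal(recomputed$in_reference_catalog, printed_occurrence)
  expect_equal(recomputed$same_donor, printed_same)
})

test_that("rendered event tables are byte-stable under input reordering", {
  events <- read_event_table(system.file("extdata",
                                         "tortoise_hgt_events.tsv",
                                         package = "hgtsieve"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  render_event_table(events, f1)
  set.seed(73)
  render_event_table(events[sample(nrow(events)), ], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  tab <- read_tsv(f1)
  expect_equal(nrow(tab), 35L)
  # single event renders header + one row
  f3 <- withr::local_tempfile(fileext = ".tsv")
  render_event_table(events[1, ], f3)
  expect_length(readLines(f3), 2L)
})
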