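test_that("local alignment matches hand-checked and oracle scores", {
  sch <- scoring_scheme()
  # MKV vs MKV: BLOSUM62 diagonal M=5, K=5, V=4
  al <- local_align(c(q = "MKV"), c(s = "MKV"), sch)
  expect_equal(al$raw_score, 14L)
  expect_equal(al$identity_count, 3L)
  expect_equal(al$identity_over_shorter, 1)
  expect_equal(al$raw_score,
               sw_oracle("MKV", "MKV", sch$submat, sch$gap_open,
                         sch$gap_extend))
  # self-alignment of any sequence has identity_over_shorter 1
  set.seed(11)
  for (len in c(5, 20, 80)) {
    s <- random_protein(len)
    self <- local_align(stats::setNames(s, "x"), stats::setNames(s, "x"), sch)
    expect_equal(self$identity_over_shorter, 1)
    expect_equal(self$aligned_query_fraction, 1)
  }
  expect_error(local_align(bio_seqs(c(a = "ACGT"), "dna"), c(b = "MKV"), sch),
               "alphabet mismatch")
})

test_that("alignment engine equals the brute-force oracle on short random pairs", {
  sch <- scoring_scheme()
  set.seed(101)
  for (r in 1:120) {
    a <- random_protein(sample(1:12, 1))
    b <- random_protein(sample(1:12, 1))
    expected <- sw_oracle(a, b, sch$submat, sch$gap_open, sch$gap_extend)
    expect_equal(local_align(stats::setNames(a, "a"),
                             stats::setNames(b, "b"), sch)$raw_score,
                 expected)
    expect_equal(as.integer(batch_scores(a, b, sch)), expected)
  }
})

test_that("alignment score is symmetric", {
  sch <- scoring_scheme()
  set.seed(5)
  for (r in 1:25) {
    a <- random_protein(sample(3:30, 1))
    b <- random_protein(sample(3:30, 1))
    expect_equal(
      local_align(stats::setNames(a, "a"), stats::setNames(b, "b"),
                  sch)$raw_score,
      local_align(stats::setNames(b, "b"), stats::setNames(a, "a"),
                  sch)$raw_score)
  }
})

test_that("bit-score conversion follows the Karlin-Altschul closed form", {
  sch <- scoring_scheme()  # lambda 0.267, K 0.041
  expect_equal(to_bits(0, sch), -log(0.041) / log(2))
  expect_equal(to_bits(0, sch), 4.60822, tolerance = 1e-5)
  expect_equal(to_bits(14, sch), (0.267 * 14 - log(0.041)) / log(2))
  expect_equal(to_bits(14, sch), 10.00103, tolerance = 1e-5)
  # strictly increasing in the raw score
  raws <- 0:50
  expect_true(all(diff(to_bits(raws, sch)) > 0))
  # E-value definition
  expect_equal(bit_evalue(10, 100, 1000), 100 * 1000 * 2^-10)
})

test_that("database search ranks deterministically and respects filters", {
  sch <- scoring_scheme()
  set.seed(21)
  base <- random_protein(60)
  seqs <- c(hit_exact = base,
            hit_close = paste0(substr(base, 1, 55), "AAAAA"),
            far1 = random_protein(60), far2 = random_protein(60))
  tax <- data.frame(id = names(seqs), partition = "Bacteria",
                    kingdom = "Bacteria", phylum_or_class = "Firmicutes",
                    stringsAsFactors = FALSE)
  db <- reference_db("Bacteria", bio_seqs(seqs, "protein"), tax)
  hits <- search_db(stats::setNames(base, "q"), db, sch)
  expect_equal(hits$subject_id[1], "hit_exact")
  expect_true(all(diff(hits$bit_score) <= 0))
  expect_true(all(hits$evalue <= 1e-3))

  # ranking is invariant under database permutation
  perm <- sample(length(seqs))
  db2 <- reference_db("Bacteria", bio_seqs(seqs[perm], "protein"), tax)
  hits2 <- search_db(stats::setNames(base, "q"), db2, sch)
  expect_identical(hits$subject_id, hits2$subject_id)

  # self-hits (identical id) are excluded
  db3 <- reference_db("Bacteria",
                      bio_seqs(c(q = base, other = seqs[["hit_close"]]),
                               "protein"),
                      data.frame(id = c("q", "other"), partition = "Bacteria",
                                 kingdom = "Bacteria",
                                 phylum_or_class = "Firmicutes"))
  hits3 <- search_db(stats::setNames(base, "q"), db3, sch)
  expect_false("q" %in% hits3$subject_id)

  # unrelated random sequences at a strict ceiling yield nothing
  strict <- search_db(stats::setNames(random_protein(40), "q"), db, sch,
                      max_evalue = 1e-20)
  expect_equal(nrow(strict), 0L)

  # empty database warns and returns an empty result
  empty_db <- structure(list(partition = "Bacteria",
                             sequences = character(0),
                             taxonomy = tax[0, ]), class = "reference_db")
  expect_message(res <- search_db(stats::setNames(base, "q"), empty_db, sch),
                 "empty database")
  expect_equal(nrow(res), 0L)
})

test_that("hit export writes the fixed column order", {
  sch <- scoring_scheme()
  base <- random_protein(50)
  seqs <- c(s1 = base, s2 = paste0(substr(base, 1, 45), "AAAAA"))
  tax <- data.frame(id = names(seqs), partition = "Bacteria",
                    kingdom = "Bacteria", phylum_or_class = "Firmicutes")
  db <- reference_db("Bacteria", bio_seqs(seqs, "protein"), tax)
  hits <- search_db(stats::setNames(base, "q"), db, sch, details = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_hits(hits, f)
  tab <- read_tsv(f)
  expect_equal(names(tab), c("query", "subject", "partition", "bits",
                             "evalue", "identity", "coverage"))
})

test_that("on simulated data vertical genes hit their own clade best", {
  sim <- simulate_hgt_data(sim_config(n_families = 40L), seed = 9L)
  sch <- scoring_scheme()
  vertical <- sim$truth$function_label[!sim$truth$is_transfer]
  ann <- sim$catalog$annotations
  one_assembly <- sim$catalog$assemblies$assembly_id[1]
  tx <- sim$catalog$transcripts[[one_assembly]]
  fungal_db <- sim$refdbs$Fungi
  correct <- 0L
  total <- 0L
  for (tid in names(tx)) {
    fl <- ann$function_label[match(tid, ann$transcript_id)]
    if (!fl %in% vertical) next
    total <- total + 1L
    best <- lapply(sim$refdbs, function(db)
      max(c(-Inf, search_db(tx[tid], db, sch)$bit_score)))
    if (names(which.max(unlist(best))) == "Fungi") correct <- correct + 1L
  }
  expect_gte(correct / total, 0.95)
})
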