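clean_read <- function(len) {
  paste(rep_len(c("A", "C", "G", "T"), len), collapse = "")
}

test_that("read screening applies every boundary rule exactly", {
  reads <- bio_seqs(c(
    len199 = clean_read(199),
    len200 = clean_read(200),
    len380 = clean_read(380),
    len381 = clean_read(381),
    homo8 = paste0(clean_read(292), strrep("A", 8)),
    homo9 = paste0(clean_read(291), strrep("A", 9)),
    ambig = paste0(clean_read(299), "N"),
    multi = paste0(strrep("A", 9), "N")), alphabet = "dna")
  out <- screen_reads(reads)
  expect_setequal(names(out$kept), c("len200", "len380", "homo8"))
  rej <- stats::setNames(out$rejected$reasons, out$rejected$read_id)
  expect_equal(rej[["len199"]], "too short")
  expect_equal(rej[["len381"]], "too long")
  expect_equal(rej[["homo9"]], "homopolymer")
  expect_equal(rej[["ambig"]], "ambiguous base")
  # every violated rule is recorded
  expect_equal(rej[["multi"]], "too short;homopolymer;ambiguous base")
})

test_that("screening is order-independent and idempotent", {
  set.seed(91)
  reads <- bio_seqs(stats::setNames(
    c(clean_read(250), clean_read(150), paste0(clean_read(250), "NN"),
      clean_read(300)),
    paste0("r", 1:4)), alphabet = "dna")
  a <- screen_reads(reads)
  b <- screen_reads(reads[sample(length(reads))])
  expect_setequal(names(a$kept), names(b$kept))
  again <- screen_reads(a$kept)
  expect_identical(names(again$kept), names(a$kept))
  expect_equal(nrow(again$rejected), 0L)
})

test_that("two-tier assignment separates similarity from placement", {
  amp <- simulate_amplicon_data(seed = 3L)
  ref1 <- names(amp$refdb)[1]
  genus1 <- unname(amp$ref_genus[ref1])
  # a read identical to a reference classifies by similarity to its genus
  read <- stats::setNames(unclass(amp$refdb)[[ref1]], "exact")
  a <- assign_two_tier(bio_seqs(c(exact = unname(read)), "dna")["exact"],
                       amp$refdb, amp$ref_genus, amp$ref_tree)
  expect_equal(a$tier, "similarity")
  expect_equal(a$genus, genus1)
  # a read at ~95% identity falls through to placement (>96% is strict)
  chars <- strsplit(unname(read), "")[[1]]
  pos <- seq(10, length(chars) - 5, length.out = ceiling(0.05 * length(chars)))
  for (p in round(pos)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  read95 <- paste(chars, collapse = "")
  b <- assign_two_tier(bio_seqs(c(r95 = read95), "dna"), amp$refdb,
                       amp$ref_genus, amp$ref_tree)
  expect_equal(b$tier, "placement")
  # a chimeric read (identical fragment + unrelated tail) fails the
  # coverage gate but places onto its source genus
  set.seed(97)
  frag <- paste0(substr(unname(read), 1, 150),
                 paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                       collapse = ""))
  chim <- assign_two_tier(bio_seqs(c(chim = frag), "dna"), amp$refdb,
                          amp$ref_genus, amp$ref_tree)
  expect_equal(chim$tier, "placement")
  expect_lt(chim$query_coverage, 0.70)
  expect_equal(chim$genus, genus1)
  # a withheld novel genus lands beyond the radius of every reference
  novel_read <- amp$samples$S1[amp$read_truth$genus[amp$read_truth$sample ==
                                                      "S1"] == "NovelGenus"]
  expect_gt(length(novel_read), 0L)
  n <- assign_two_tier(novel_read[1], amp$refdb, amp$ref_genus, amp$ref_tree)
  expect_equal(n$genus, "novel-lineage")
  expect_equal(n$tier, "placement")
  expect_error(assign_two_tier(novel_read[1], bio_seqs(character(0), "dna"),
                               amp$ref_genus), "empty reference")
})

test_that("tier-1 calls are invariant to reference database shuffling", {
  amp <- simulate_amplicon_data(seed = 7L)
  reads <- amp$samples$S2[1:5]
  set.seed(93)
  perm <- sample(length(amp$refdb))
  for (i in seq_along(reads)) {
    a <- assign_two_tier(reads[i], amp$refdb, amp$ref_genus)
    b <- assign_two_tier(reads[i], amp$refdb[perm], amp$ref_genus)
    expect_identical(a$genus, b$genus)
    expect_identical(a$tier, b$tier)
  }
})

test_that("community tables conserve classified reads per sample", {
  amp <- simulate_amplicon_data(seed = 11L)
  assignments <- do.call(rbind, lapply(names(amp$samples), function(sid) {
    out <- assign_reads(amp$samples[[sid]], refdb = amp$refdb,
                        ref_genus = amp$ref_genus, ref_tree = amp$ref_tree)
    out$sample <- sid
    out
  }))
  tab <- community_table(assignments)
  expect_equal(unname(colSums(tab)),
               unname(vapply(amp$samples, length, integer(1))))
  # a single-genus sample fills a single cell
  solo <- data.frame(sample = "X", genus = rep("GenusA", 10))
  tab2 <- community_table(solo)
  expect_equal(dim(tab2), c(1L, 1L))
  expect_equal(tab2[1, 1], 10L)
  # the withheld genus surfaces as novel-lineage with the right count
  truth_novel <- sum(amp$read_truth$genus == "NovelGenus" &
                       amp$read_truth$sample == "S1")
  expect_equal(tab["novel-lineage", "S1"], truth_novel)
  # known-genus counts recover the sampled community (drawn counts are the
  # sampling truth; classification noise stays within a few reads)
  truth_tab <- table(factor(amp$read_truth$genus, levels = rownames(tab)),
                     amp$read_truth$sample)
  known <- setdiff(rownames(tab), "novel-lineage")
  expect_true(all(abs(tab[known, colnames(tab)] -
                        truth_tab[known, colnames(tab)]) <= 3))
})
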