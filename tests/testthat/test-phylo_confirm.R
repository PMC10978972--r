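test_that("progressive alignment handles identity and length invariants", {
  sch <- scoring_scheme()
  set.seed(51)
  s <- random_protein(40)
  # two identical sequences align without gaps
  msa <- progressive_align(bio_seqs(c(a = s, b = s)), sch)
  expect_false(any(grepl("-", unclass(msa), fixed = TRUE)))
  expect_equal(unname(nchar(msa)), c(40L, 40L))
  # single sequence: identity alignment
  one <- progressive_align(bio_seqs(c(only = s)), sch)
  expect_equal(unname(as.character(one)), s)
  # alignment length is at least the longest input
  seqs <- bio_seqs(c(a = random_protein(30), b = random_protein(50),
                     c = random_protein(45)))
  msa2 <- progressive_align(seqs, sch)
  expect_gte(nchar(msa2[[1]]), 50L)
  expect_equal(length(unique(nchar(msa2))), 1L)
  # gap-stripped rows reproduce the inputs
  expect_identical(
    stats::setNames(gsub("-", "", as.character(msa2), fixed = TRUE),
                    names(msa2)),
    stats::setNames(as.character(seqs), names(seqs)))
})

test_that("adding an identical duplicate never lowers the sum-of-pairs score", {
  sch <- scoring_scheme()
  set.seed(53)
  for (r in 1:5) {
    base <- random_protein(35)
    mutate <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), k)
      ch[idx] <- vapply(ch[idx], function(c) setdiff(AA_LETTERS, c)[1], "")
      paste(ch, collapse = "")
    }
    seqs <- c(a = base, b = mutate(base, 4), c = mutate(base, 6))
    sp0 <- sum_of_pairs(progressive_align(bio_seqs(seqs), sch), sch)
    with_dup <- c(seqs, a2 = base)
    sp1 <- sum_of_pairs(progressive_align(bio_seqs(with_dup), sch), sch)
    expect_gte(sp1, sp0)
  }
})

test_that("NJ recovers additive trees and normalizes bootstrap supports", {
  set.seed(55)
  # additive 4-taxon matrix: NJ recovers the generating split
  gen <- random_additive_matrix(4)
  tr <- ape::nj(gen$d)
  expect_equal(phangorn::RF.dist(tr, gen$tree), 0)
  # identical sequences give zero branch lengths
  s <- random_protein(30)
  msa <- progressive_align(bio_seqs(c(a = s, b = s, c = s, d = s)))
  phy <- nj_tree(msa, bootstrap_n = 20L, seed = 2L)
  expect_true(all(phy$tree$edge.length == 0))
  # supports lie in [0,1]; an unambiguous alignment yields support 1 for
  # its generating split
  seqs <- bio_seqs(c(
    a = strrep("A", 30), b = paste0(strrep("A", 25), strrep("W", 5)),
    c = strrep("L", 30), d = paste0(strrep("L", 25), strrep("F", 5))))
  msa2 <- progressive_align(seqs)
  phy2 <- nj_tree(msa2, bootstrap_n = 50L, seed = 3L)
  expect_true(all(phy2$split_support >= 0 & phy2$split_support <= 1))
  expect_equal(clade_support(phy2, c("a", "b")), 1)
})

test_that("NJ equals brute-force minimum-evolution search up to 6 taxa", {
  set.seed(57)
  for (n in 4:6) {
    for (r in 1:3) {
      gen <- random_additive_matrix(n)
      nj <- ape::nj(gen$d)
      best <- me_best_topology(gen$d)
      expect_equal(phangorn::RF.dist(nj, best), 0)
    }
  }
})

test_that("hit sets pool the two searches with deduplication", {
  pool <- stats::setNames(
    vapply(1:6, function(i) random_protein(30), ""),
    paste0("ref", 1:6))
  mk_hits <- function(ids, ev) {
    data.frame(query_id = "q", subject_id = ids, partition = "Bacteria",
               raw_score = 100, bit_score = 50, evalue = ev,
               stringsAsFactors = FALSE)
  }
  q <- stats::setNames(random_protein(30), "q")
  hs <- build_hit_set(q, mk_hits(c("ref1", "ref2", "ref3"), 1e-20),
                      mk_hits(c("ref2", "ref4"), 1e-20),
                      sequence_pool = pool)
  expect_setequal(names(hs), c("q", "ref1", "ref2", "ref3", "ref4"))
  # hits above the E-value ceiling are dropped; with none left, only the
  # query (and refs) remain and the no-homologs reason is set
  hs2 <- build_hit_set(q, mk_hits("ref1", 1e-3), mk_hits("ref2", 1e-3),
                       sequence_pool = pool)
  expect_equal(names(hs2), "q")
  expect_equal(attr(hs2, "reason"), "no homologs")
  # max_per_search truncates each list
  hs3 <- build_hit_set(q, mk_hits(paste0("ref", 1:6), 1e-20), NULL,
                       sequence_pool = pool, max_per_search = 2L)
  expect_setequal(names(hs3), c("q", "ref1", "ref2"))
})

test_that("nesting verdicts follow support, purity and donor rules", {
  taxa <- data.frame(
    id = c("query", "f1", "f2", "f3", "fun1", "fun2", "b1", "b2"),
    partition = c("AGF", "Bacteria", "Bacteria", "Bacteria", "Fungi",
                  "Fungi", "Bacteria", "Bacteria"),
    kingdom = c("Neocallimastigomycota", "Bacteria", "Bacteria", "Bacteria",
                "Fungi", "Fungi", "Bacteria", "Bacteria"),
    phylum_or_class = c("Neocallimastigomycota", "Firmicutes", "Firmicutes",
                        "Firmicutes", "Ascomycota", "Ascomycota",
                        "Firmicutes", "Bacteroidetes"),
    stringsAsFactors = FALSE)
  # query nested inside a supported 3-tip Firmicutes clade
  tr <- ape::read.tree(text = paste0(
    "((query:0.05,(f1:0.05,f2:0.05)0.9:0.05)0.95:0.3,",
    "(f3:0.1,(fun1:0.3,fun2:0.3)0.9:0.2)0.8:0.3);"))
  phy <- hgt_phylogeny(tr, tip_taxa = taxa)
  v <- assess_nesting(phy, "query")
  expect_true(v$is_hgt)
  expect_equal(v$donor_kingdom, "Bacteria")
  expect_equal(v$donor_phylum, "Firmicutes")
  expect_equal(v$defining_support, 0.95)
  # same topology with weak support at the defining split fails
  tr_weak <- ape::read.tree(text = paste0(
    "((query:0.05,(f1:0.05,f2:0.05)0.9:0.05)0.5:0.3,",
    "(f3:0.1,(fun1:0.3,fun2:0.3)0.9:0.2)0.8:0.3);"))
  v2 <- assess_nesting(hgt_phylogeny(tr_weak, tip_taxa = taxa), "query")
  expect_false(v2$is_hgt)
  expect_equal(v2$reason, "insufficient support")
  # query sister to the fungal clade: congruent, no transfer
  tr_fun <- ape::read.tree(text = paste0(
    "((query:0.1,(fun1:0.05,fun2:0.05)0.9:0.05)0.9:0.2,",
    "(b1:0.3,b2:0.3)0.9:0.2);"))
  v3 <- assess_nesting(hgt_phylogeny(tr_fun, tip_taxa = taxa), "query")
  expect_false(v3$is_hgt)
  # donor tips spanning two phyla of one kingdom: Mixed phyla
  tr_mix <- ape::read.tree(text = paste0(
    "((query:0.05,(f1:0.05,b2:0.05)0.9:0.05)0.95:0.3,",
    "(fun1:0.3,fun2:0.3)0.9:0.3);"))
  v4 <- assess_nesting(hgt_phylogeny(tr_mix, tip_taxa = taxa), "query")
  expect_true(v4$is_hgt)
  expect_equal(v4$donor_phylum, "Mixed phyla")
  expect_equal(v4$donor_kingdom, "Bacteria")
  # impure clade at full purity fails, passes at relaxed purity
  tr_imp <- ape::read.tree(text = paste0(
    "((query:0.05,(f1:0.05,(f2:0.05,fun1:0.05)0.9:0.02)0.9:0.05)0.95:0.3,",
    "(fun2:0.3,(b1:0.2,b2:0.2)0.9:0.1)0.8:0.3);"))
  v5 <- assess_nesting(hgt_phylogeny(tr_imp, tip_taxa = taxa), "query",
                       purity = 1.0)
  expect_false(v5$is_hgt)
  v6 <- assess_nesting(hgt_phylogeny(tr_imp, tip_taxa = taxa), "query",
                       purity = 0.6)
  expect_true(v6$is_hgt)
  # unknown query tips are rejected
  expect_error(assess_nesting(phy, "ghost"), "not a tip")
})

test_that("cluster members do not count against donor purity", {
  taxa <- data.frame(
    id = c("q1", "q2", "f1", "f2", "fun1", "fun2"),
    partition = c("AGF", "AGF", "Bacteria", "Bacteria", "Fungi", "Fungi"),
    kingdom = c("Neocallimastigomycota", "Neocallimastigomycota",
                "Bacteria", "Bacteria", "Fungi", "Fungi"),
    phylum_or_class = c("Neocallimastigomycota", "Neocallimastigomycota",
                        "Firmicutes", "Firmicutes", "Ascomycota",
                        "Ascomycota"),
    stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = paste0(
    "(((q1:0.02,q2:0.02)0.99:0.03,(f1:0.05,f2:0.05)0.9:0.05)0.95:0.3,",
    "(fun1:0.3,fun2:0.3)0.9:0.3);"))
  phy <- hgt_phylogeny(tr, tip_taxa = taxa)
  # without the cluster annotation, q2 (a fungal-lineage tip) breaks purity
  v_single <- assess_nesting(phy, "q1")
  expect_false(v_single$is_hgt)
  # with it, the verdict sees a pure Firmicutes neighborhood
  v_cluster <- assess_nesting(phy, "q1", cluster_ids = c("q1", "q2"))
  expect_true(v_cluster$is_hgt)
  expect_equal(v_cluster$donor_phylum, "Firmicutes")
})

test_that("verdicts are deterministic given the seed", {
  set.seed(59)
  base <- random_protein(60)
  mutate <- function(s, t) paste(
    vapply(strsplit(s, "")[[1]], function(c)
      if (runif(1) < t) sample(setdiff(AA_LETTERS, c), 1) else c, ""),
    collapse = "")
  seqs <- bio_seqs(c(q = mutate(base, 0.05), d1 = base, d2 = mutate(base, 0.1),
                     o1 = mutate(base, 0.5), o2 = mutate(base, 0.5)))
  taxa <- data.frame(id = names(seqs),
                     partition = c("AGF", rep("Bacteria", 2), rep("Fungi", 2)),
                     kingdom = c("Neocallimastigomycota", rep("Bacteria", 2),
                                 rep("Fungi", 2)),
                     phylum_or_class = c("Neocallimastigomycota",
                                         rep("Firmicutes", 2),
                                         rep("Ascomycota", 2)),
                     stringsAsFactors = FALSE)
  msa <- progressive_align(seqs)
  p1 <- nj_tree(msa, bootstrap_n = 30L, seed = 77L, tip_taxa = taxa)
  p2 <- nj_tree(msa, bootstrap_n = 30L, seed = 77L, tip_taxa = taxa)
  v1 <- assess_nesting(p1, "q")
  v2 <- assess_nesting(p2, "q")
  expect_identical(v1[c("is_hgt", "defining_support", "donor_kingdom",
                        "donor_phylum")],
                   v2[c("is_hgt", "defining_support", "donor_kingdom",
                        "donor_phylum")])
})
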