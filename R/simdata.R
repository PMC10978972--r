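#' Simulation configuration
#'
#' Defines the study conditions the planted-transfer benchmark emulates:
#' per-assembly proteomes from two closely related tortoise-associated
#' genera (5 and 2 transcriptomic assemblies) whose gene families are mostly
#' vertically inherited fungal-like genes, plus a minority grafted from
#' bacterial donor lineages, searched against taxonomy-partitioned reference
#' databases built from the other tips of a fixed labeled species tree.
#'
#' Defaults: 200 gene families; root lengths uniform on 150-600 aa; 5% of
#' families planted as transfers; post-transfer divergence 0.05 expected
#' substitutions/site; per-genus divergence 0.01; each planted event present
#' in each assembly of either genus with probability 0.8; uniform amino-acid
#' background frequencies (the substitution process is a Poisson
#' change/uniform replacement model, chosen because it is exactly
#' analyzable).
#'
#' @param n_families number of gene families
#' @param root_length_range integer range of root sequence lengths (aa)
#' @param transfer_fraction probability a family is a planted transfer
#' @param post_transfer_divergence branch length from the donor tip to the
#'   transferred AGF copy (expected substitutions/site)
#' @param genus_divergence branch length from the AGF ancestor (or the
#'   transferred copy) to each genus-level sequence
#' @param genera named integer vector: genus label -> number of assemblies
#' @param event_prevalence probability a planted event is realized in each
#'   assembly of a genus
#' @param cazy_fraction probability a family carries a CAZy annotation
#' @param background_frequencies amino-acid distribution for roots and
#'   replacements (length 20, sums to 1)
#' @param species_tree fixed labeled topology with branch lengths
#'   (ape `phylo`); tip "AGF" is the focal lineage
#' @param ingroup_partition partition label of the fungal ingroup database
#' @return a `sim_config` object
#' @export
sim_config <- function(n_families = 200L,
                       root_length_range = c(150L, 600L),
                       transfer_fraction = 0.05,
                       post_transfer_divergence = 0.05,
                       genus_divergence = 0.01,
                       genera = c(T = 5L, B = 2L),
                       event_prevalence = 0.8,
                       cazy_fraction = 0.1,
                       background_frequencies = rep(1 / 20, 20),
                       species_tree = default_species_tree(),
                       ingroup_partition = "Fungi") {
  stopifnot(transfer_fraction >= 0, transfer_fraction < 1,
            event_prevalence > 0, event_prevalence <= 1,
            all(species_tree$edge.length > 0),
            post_transfer_divergence > 0, genus_divergence >= 0,
            length(background_frequencies) == 20,
            abs(sum(background_frequencies) - 1) < 1e-8,
            root_length_range[1] >= 1,
            root_length_range[2] >= root_length_range[1],
            length(genera) >= 1, all(genera >= 1))
  structure(list(n_families = as.integer(n_families),
                 root_length_range = as.integer(root_length_range),
                 transfer_fraction = transfer_fraction,
                 post_transfer_divergence = post_transfer_divergence,
                 genus_divergence = genus_divergence,
                 genera = genera,
                 event_prevalence = event_prevalence,
                 cazy_fraction = cazy_fraction,
                 background_frequencies = background_frequencies,
                 species_tree = species_tree,
                 ingroup_partition = ingroup_partition),
            class = "sim_config")
}

#' Default simulated species tree
#'
#' Seven labeled tips: three bacterial phyla, one metazoan, one plant, the
#' non-Neocallimastigomycota fungal ingroup, and the AGF lineage. Branch
#' lengths (expected substitutions/site) are set so that vertical AGF genes
#' retain strong fungal ingroup hits (~75% identity), moderate plant/animal
#' hits, and essentially random bacterial similarity, while genes grafted
#' from a bacterial tip stay ~95% identical to their donor.
#'
#' @return an ape `phylo` tree
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((Firmicutes:0.25,(Bacteroidetes:0.2,Proteobacteria:0.2):0.1):0.9,",
    "(Metazoa:0.35,(Viridiplantae:0.35,(Fungi:0.15,AGF:0.15):0.1):0.05):0.55);"))
}

# lineages of the reference tips of the default species tree
sim_reference_lineages <- function() {
  data.frame(
    tip = c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Metazoa",
            "Viridiplantae", "Fungi"),
    partition = c("Bacteria", "Bacteria", "Bacteria", "Metazoa",
                  "Viridiplantae", "Fungi"),
    kingdom = c("Bacteria", "Bacteria", "Bacteria", "Metazoa",
                "Viridiplantae", "Fungi"),
    phylum_or_class = c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                        "Chordata", "Streptophyta", "Ascomycota"),
    stringsAsFactors = FALSE)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# Poisson change / uniform-replacement substitution along one branch: each
# site substitutes with probability 1 - exp(-t); the new residue is drawn
# from the background excluding the current one.
evolve_seq <- function(chars, t, freqs) {
  if (t <= 0) return(chars)
  n <- length(chars)
  hit <- runif(n) < (1 - exp(-t))
  if (!any(hit)) return(chars)
  idx <- which(hit)
  for (i in idx) {
    w <- freqs
    w[AA20 == chars[i]] <- 0
    chars[i] <- sample(AA20, 1L, prob = w)
  }
  chars
}

#' Evolve a gene family along a tree
#'
#' Starting from the root sequence, substitutes sites independently along
#' each branch (probability `1 - exp(-t * rate_scale)` per site) with
#' replacement residues drawn from the background frequencies excluding the
#' current residue. Deterministic given the RNG state.
#'
#' @param root character string, the root protein sequence
#' @param tree ape `phylo` with branch lengths
#' @param rate_scale multiplier applied to branch lengths
#' @param freqs amino-acid background frequencies
#' @return named character vector of tip sequences
#' @export
evolve_family <- function(root, tree, rate_scale = 1,
                          freqs = rep(1 / 20, 20)) {
  ntip <- ape::Ntip(tree)
  root_node <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root_node]] <- strsplit(root, "")[[1]]
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    seqs[[child]] <- evolve_seq(seqs[[par]], ord$edge.length[e] * rate_scale,
                                freqs)
  }
  tips <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                 character(1))
  stats::setNames(tips, tree$tip.label)
}

#' Simulate proteomes with planted transfers
#'
#' Generates, for each gene family, tip sequences along the species tree;
#' reference databases are built from the non-AGF tips (partitioned by
#' lineage). The AGF copy is vertically inherited except for a random subset
#' of families (probability `transfer_fraction`), whose AGF copy is replaced
#' by a descendant of a random bacterial donor tip evolved by
#' `post_transfer_divergence`. Genus-level copies diverge by
#' `genus_divergence`; every assembly carries the vertical genes, while each
#' planted event is present in each assembly with probability
#' `event_prevalence` (assemblies missing the event lack the gene, modeling
#' gene loss). Byte-identical outputs for identical config + seed.
#'
#' @param config a [sim_config()]
#' @param seed RNG seed
#' @return a `hgt_simulation` list: `catalog` (an [assembly_catalog()]),
#'   `refdbs` (named list of [reference_db()]), `taxonomy` (data frame),
#'   `truth` (truth table data frame), `config`, `seed`
#' @export
simulate_hgt_data <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tree <- config$species_tree
  lin <- sim_reference_lineages()
  bacteria_tips <- lin$tip[lin$kingdom == "Bacteria"]
  genera <- config$genera
  assemblies <- data.frame(
    assembly_id = unlist(lapply(names(genera), function(g)
      sprintf("%s%d", g, seq_len(genera[[g]])))),
    genus = rep(names(genera), genera),
    stringsAsFactors = FALSE)
  freqs <- config$background_frequencies
  n_fam <- config$n_families
  ref_rows <- vector("list", n_fam)
  tx_per_assembly <- stats::setNames(
    rep(list(character(0)), nrow(assemblies)), assemblies$assembly_id)
  ann_rows <- vector("list", 0L)
  truth_rows <- vector("list", n_fam)
  cog_pool <- c("[E] Amino acid transport and metabolism",
                "[C] Energy production and conversion",
                "[G] Carbohydrate transport and metabolism",
                "[J] Translation, ribosomal structure and biogenesis",
                "[R] General function prediction only")
  cazy_pool <- c("GH5", "GH10", "GH13", "GH43", "GH48", "CE1", "CE4", "PL1",
                 "PL4")
  for (i in seq_len(n_fam)) {
    L <- sample(seq(config$root_length_range[1], config$root_length_range[2]),
                1L)
    root <- paste(sample(AA20, L, replace = TRUE, prob = freqs),
                  collapse = "")
    tips <- evolve_family(root, tree, freqs = freqs)
    is_transfer <- runif(1) < config$transfer_fraction
    donor_tip <- NA_character_
    base <- tips[["AGF"]]
    if (is_transfer) {
      donor_tip <- sample(bacteria_tips, 1L)
      base <- paste(evolve_seq(strsplit(tips[[donor_tip]], "")[[1]],
                               config$post_transfer_divergence, freqs),
                    collapse = "")
    }
    genus_seq <- stats::setNames(vapply(names(genera), function(g) {
      paste(evolve_seq(strsplit(base, "")[[1]], config$genus_divergence,
                       freqs), collapse = "")
    }, character(1)), names(genera))
    is_cazy <- runif(1) < config$cazy_fraction
    cazy <- if (is_cazy) sample(cazy_pool, 1L) else NA_character_
    func <- sprintf("family-%04d", i)
    cog <- sample(cog_pool, 1L)
    carried <- character(0)
    for (a in seq_len(nrow(assemblies))) {
      aid <- assemblies$assembly_id[a]
      present <- if (is_transfer) runif(1) < config$event_prevalence else TRUE
      if (!present) next
      tid <- sprintf("%s_tx%04d", aid, i)
      tx_per_assembly[[aid]][tid] <- genus_seq[[assemblies$genus[a]]]
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        transcript_id = tid, function_label = func, cog_class = cog,
        cazy_family = cazy, stringsAsFactors = FALSE)
      carried <- c(carried, aid)
    }
    ref_rows[[i]] <- data.frame(
      id = sprintf("%s_f%04d", lin$tip, i), tip = lin$tip,
      seq = unname(tips[lin$tip]), stringsAsFactors = FALSE)
    donor_lin <- if (is_transfer) lin[lin$tip == donor_tip, ] else NULL
    truth_rows[[i]] <- data.frame(
      family = i, function_label = func, is_transfer = is_transfer,
      donor_tip = donor_tip,
      donor_kingdom = if (is_transfer) donor_lin$kingdom else NA_character_,
      donor_phylum = if (is_transfer) donor_lin$phylum_or_class else
        NA_character_,
      is_cazy = is_cazy, cazy_family = cazy,
      n_assemblies = length(carried),
      assemblies = paste(carried, collapse = ";"),
      prevalence_realized = length(carried) / nrow(assemblies),
      stringsAsFactors = FALSE)
  }
  refs <- do.call(rbind, ref_rows)
  taxonomy <- data.frame(
    id = refs$id,
    partition = lin$partition[match(refs$tip, lin$tip)],
    kingdom = lin$kingdom[match(refs$tip, lin$tip)],
    phylum_or_class = lin$phylum_or_class[match(refs$tip, lin$tip)],
    stringsAsFactors = FALSE)
  refdbs <- lapply(split(seq_len(nrow(refs)), taxonomy$partition),
                   function(idx) {
    part <- taxonomy$partition[idx[1]]
    seqs <- bio_seqs(stats::setNames(refs$seq[idx], refs$id[idx]),
                     alphabet = "protein")
    reference_db(part, seqs, taxonomy[idx, c("id", "partition", "kingdom",
                                             "phylum_or_class")])
  })
  transcripts <- lapply(tx_per_assembly, function(v)
    bio_seqs(v, alphabet = "protein"))
  catalog <- assembly_catalog(assemblies, transcripts,
                              do.call(rbind, ann_rows))
  structure(list(catalog = catalog, refdbs = refdbs, taxonomy = taxonomy,
                 truth = do.call(rbind, truth_rows), config = config,
                 seed = seed),
            class = "hgt_simulation")
}

#' @export
print.hgt_simulation <- function(x, ...) {
  cat(sprintf(
    "hgt_simulation (seed %d): %d families (%d planted transfers), %d assemblies\n",
    x$seed, nrow(x$truth), sum(x$truth$is_transfer),
    nrow(x$catalog$assemblies)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits per-assembly proteome FASTAs, per-partition reference FASTAs, the
#' taxonomy TSV, the annotation TSV, the truth TSV, and the species tree in
#' Newick format. All outputs are byte-deterministic.
#'
#' @param sim a `hgt_simulation`
#' @param dir output directory (created if absent)
#' @return invisibly, the vector of files written
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (aid in names(sim$catalog$transcripts)) {
    f <- file.path(dir, paste0("assembly_", aid, ".faa"))
    write_fasta(sim$catalog$transcripts[[aid]], f)
    files <- c(files, f)
  }
  for (part in names(sim$refdbs)) {
    f <- file.path(dir, paste0("refdb_", part, ".faa"))
    write_fasta(sim$refdbs[[part]]$sequences, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "taxonomy.tsv")
  write_tsv(sim$taxonomy, f)
  files <- c(files, f)
  f <- file.path(dir, "annotations.tsv")
  write_tsv(sim$catalog$annotations, f)
  files <- c(files, f)
  f <- file.path(dir, "truth.tsv")
  write_tsv(sim$truth, f)
  files <- c(files, f)
  f <- file.path(dir, "species_tree.nwk")
  ape::write.tree(sim$config$species_tree, file = f)
  files <- c(files, f)
  invisible(files)
}

#' Simulate an LSU-like amplicon benchmark
#'
#' Emits nucleotide reference sequences for a set of AGF-like genera (one
#' representative each), a reference tree over them, and per-sample reads
#' drawn from known genus proportions with small sequencing divergence. One
#' genus is withheld from the reference database to exercise the
#' novel-lineage path of the two-tier classifier.
#'
#' @param n_genera number of reference genera
#' @param n_samples number of samples
#' @param reads_per_sample reads drawn per sample
#' @param read_divergence per-read divergence from its genus reference
#' @param genus_divergence divergence of each genus from the shared ancestor
#' @param amplicon_length reference amplicon length (bp)
#' @param seed RNG seed
#' @return list: `refdb` (a [bio_seqs]), `ref_genus` (named genus labels),
#'   `ref_tree` (ape phylo), `samples` (list of [bio_seqs] per sample),
#'   `read_truth` (data frame sample/read/genus), `proportions`
#'   (genus x sample matrix of sampling probabilities), `novel_genus`
#' @export
simulate_amplicon_data <- function(n_genera = 6L, n_samples = 3L,
                                   reads_per_sample = 60L,
                                   read_divergence = 0.01,
                                   genus_divergence = 0.08,
                                   amplicon_length = 340L, seed = 1L) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  mutate_nt <- function(chars, t) {
    hit <- runif(length(chars)) < (1 - exp(-t))
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(nt, chars[i]), 1L)
    }
    chars
  }
  root <- sample(nt, amplicon_length, replace = TRUE)
  genus_names <- c(sprintf("Genus%02d", seq_len(n_genera)), "NovelGenus")
  refs <- lapply(genus_names, function(g)
    paste(mutate_nt(root, genus_divergence), collapse = ""))
  names(refs) <- paste0("ref_", genus_names)
  ref_genus <- stats::setNames(genus_names, names(refs))
  known <- names(refs)[genus_names != "NovelGenus"]
  refdb <- bio_seqs(unlist(refs[known]), alphabet = "dna")
  # reference tree over the known references (NJ on p-distances)
  refmat <- do.call(rbind, strsplit(unlist(refs[known]), ""))
  n <- nrow(refmat)
  d <- matrix(0, n, n, dimnames = list(known, known))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(refmat[i, ] != refmat[j, ])
    }
  }
  ref_tree <- ape::nj(as.dist(d))
  # per-sample genus proportions (novel genus present in sample 1 only)
  props <- matrix(0, length(genus_names), n_samples,
                  dimnames = list(genus_names,
                                  sprintf("S%d", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    w <- runif(n_genera)
    props[seq_len(n_genera), s] <- w / sum(w)
  }
  props[, 1] <- props[, 1] * 0.8
  props["NovelGenus", 1] <- 0.2
  samples <- list()
  read_truth <- list()
  for (s in seq_len(n_samples)) {
    sid <- colnames(props)[s]
    picks <- sample(genus_names, reads_per_sample, replace = TRUE,
                    prob = props[, s])
    reads <- vapply(seq_along(picks), function(r) {
      src <- strsplit(refs[[paste0("ref_", picks[r])]], "")[[1]]
      paste(mutate_nt(src, read_divergence), collapse = "")
    }, character(1))
    names(reads) <- sprintf("%s_read%03d", sid, seq_along(reads))
    samples[[sid]] <- bio_seqs(reads, alphabet = "dna")
    read_truth[[s]] <- data.frame(sample = sid, read_id = names(reads),
                                  genus = picks, stringsAsFactors = FALSE)
  }
  list(refdb = refdb, ref_genus = ref_genus[known], ref_tree = ref_tree,
       samples = samples, read_truth = do.call(rbind, read_truth),
       proportions = props, novel_genus = "NovelGenus")
}
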