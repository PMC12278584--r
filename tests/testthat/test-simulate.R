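test_that("species-tree simulation honors branch-length constraints", {
  cfg4 <- sim_config(n_taxa = 4, n_loci = 1, short_branch_fraction = 0,
                     occupancy_range = c(4, 4), seed = 3)
  tr <- simulate_species_tree(cfg4)
  ntip <- length(tr$tip.label)
  internal <- which(tr$edge[, 2] > ntip)
  expect_equal(length(internal), 2)
  expect_true(all(tr$edge.length[internal] >= 0.1))
  expect_identical(tree_units(tr), "coalescent")

  cfg20 <- sim_config(n_taxa = 20, n_loci = 1, short_branch_fraction = 0.5,
                      occupancy_range = c(4, 20), seed = 5)
  tr20 <- simulate_species_tree(cfg20)
  internal20 <- which(tr20$edge[, 2] > 20)
  expect_gte(sum(tr20$edge.length[internal20] < 0.1), 9)

  cfg12 <- sim_config(n_taxa = 12, n_loci = 1, occupancy_range = c(4, 12),
                      seed = 7)
  expect_identical(ape::write.tree(simulate_species_tree(cfg12)),
                   ape::write.tree(simulate_species_tree(cfg12)))
  expect_error(simulate_species_tree(
    sim_config(n_taxa = 3, occupancy_range = c(4, 4))), ">= 4")
})

test_that("MSC gene trees are concordant when coalescence is immediate", {
  st <- coal_tree("(((A:40,B:40):20,C:60):20,D:80);")
  gts <- simulate_gene_trees(st, 100, seed = 2)
  rfs <- vapply(gts, function(g) gtdiscord::rf_distance(g, st), numeric(1))
  expect_true(all(rfs == 0))
})

test_that("MSC triple frequencies follow 1 - (2/3) exp(-x)", {
  n <- 1500
  for (x in c(0, 0.25, 1)) {
    st <- coal_tree(sprintf("(((A:1,B:1):%g,C:%g):1,D:%g);",
                            x, 1 + x, 2 + x))
    gts <- simulate_gene_trees(st, n, seed = 31 + round(100 * x))
    p <- 1 - (2 / 3) * exp(-x)
    obs <- triple_freq(gts, "A", "B", "C")
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-12)
    if (x == 0) {
      # star symmetry: each alternative near 1/3
      alt <- triple_freq(gts, "A", "C", "B")
      expect_lt(abs(alt - 1 / 3), 3 * sqrt(2 / 9 / n))
    }
  }
})

test_that("gene-tree simulation validates units", {
  st <- coal_tree("((A:1,B:1):1,C:2);")
  attr(st, "units") <- NULL
  expect_error(simulate_gene_trees(st, 2), "coalescent units")
  st2 <- ape::read.tree(text = "((A,B),C);")
  attr(st2, "units") <- "coalescent"
  expect_error(simulate_gene_trees(st2, 2), "no branch lengths")
})

test_that("zero-length trees copy the root sequence to every tip", {
  tr <- subst_tree(ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);"))
  m <- fmutsel0_model(gtr_model(freq = c(.3, .2, .2, .3)),
                      fitness = rnorm(20), omega = 1)
  aln <- simulate_codon_alignment(tr, m, 50, seed = 9)
  expect_true(all(apply(aln$states, 2, function(col) length(unique(col))) == 1))
})

test_that("simulated nucleotide frequencies converge to stationarity", {
  gm <- gtr_model(rates = c(1.4, 2.4, 0.6, 1.1, 3.1, 1),
                  freq = c(.35, .15, .2, .3))
  tr <- subst_tree(ape::read.tree(text = "((a:0.3,b:0.3):0.2,c:0.5);"))
  aln <- simulate_codon_alignment(tr, gm, 10000, seed = 13)
  for (nt in 1:4) {
    obs <- mean(aln$states == nt)
    p <- gm$freq[nt]
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / (3 * 10000)))
  }
})

test_that("selection-free FMutSel0 sequences follow mutation-layer codon frequencies", {
  mut <- gtr_model(freq = c(.3, .2, .2, .3))
  m <- fmutsel0_model(mut, fitness = rep(0, 20), omega = 1)
  tr <- subst_tree(ape::read.tree(text = "(a:0.2,b:0.2);"))
  aln <- simulate_codon_alignment(tr, m, 8000, seed = 17)
  mutfreq <- gtdiscord:::.codon_mut_freq(mut$freq)
  # spot-check the most common codons
  for (idx in order(mutfreq, decreasing = TRUE)[1:5]) {
    obs <- mean(aln$states == idx)
    p <- mutfreq[idx]
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 16000))
  }
  expect_false(any(is.na(aln$states)))   # sense codons only
})

test_that("occupancy thinning respects bounds, outgroup and determinism", {
  cfg <- sim_config(n_taxa = 20, n_loci = 1, occupancy_range = c(8, 10),
                    seed = 2)
  st <- simulate_species_tree(cfg)
  gt <- simulate_gene_trees(st, 1, seed = 3)[[1]]
  m <- gtr_model()
  aln <- simulate_codon_alignment(scale_to_substitutions(gt, 0.1), m, 30,
                                  seed = 4)
  og <- st$tip.label[1]
  counts <- vapply(1:50, function(i) {
    th <- thin_taxa(aln, gt, c(8, 10), og, seed = i)
    expect_true(og %in% th$aln$taxa)
    expect_setequal(th$tree$tip.label, th$aln$taxa)
    length(th$aln$taxa)
  }, numeric(1))
  expect_true(all(counts >= 8 & counts <= 10))
  t1 <- thin_taxa(aln, gt, c(8, 10), og, seed = 7)
  t2 <- thin_taxa(aln, gt, c(8, 10), og, seed = 7)
  expect_identical(t1$aln$taxa, t2$aln$taxa)
  # identity when the range pins the full taxon set
  full <- thin_taxa(aln, gt, c(20, 20), og, seed = 1)
  expect_setequal(full$aln$taxa, aln$taxa)
  expect_error(thin_taxa(aln, gt, c(8, 10), "nope", seed = 1),
               "absent from alignment")
})

test_that("locus-set simulation is reproducible and writes clean artifacts", {
  cfg <- sim_config(n_taxa = 8, n_loci = 3, n_codons_range = c(20, 40),
                    occupancy_range = c(5, 8), subst_scale = 0.3, seed = 41)
  s1 <- simulate_locus_set(cfg)
  s2 <- simulate_locus_set(cfg)
  expect_identical(ape::write.tree(s1$species_tree),
                   ape::write.tree(s2$species_tree))
  expect_identical(s1$loci[[2]]$aln$states, s2$loci[[2]]$aln$states)
  d <- tempfile()
  man <- write_locus_set(s1, d)
  expect_equal(nrow(man), 3)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  rt <- read_codon_fasta(file.path(d, paste0(s1$loci[[1]]$aln$id, ".fasta")))
  expect_equal(rt$states[s1$loci[[1]]$aln$taxa, ],
               s1$loci[[1]]$aln$states[s1$loci[[1]]$aln$taxa, ])
  unlink(d, recursive = TRUE)
})
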