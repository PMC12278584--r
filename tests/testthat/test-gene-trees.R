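test_that("four-taxon search matches exhaustive scoring of the 3 topologies", {
  gm <- gtr_model(freq = c(.3, .2, .2, .3))
  truth <- subst_tree(ape::read.tree(text = "((a:0.3,b:0.3):0.25,(c:0.3,d:0.3):0.05);"))
  aln <- simulate_codon_alignment(truth, gm, 400, seed = 6)
  est <- infer_gene_tree(aln, gm, seed = 1)
  topos <- list(ape::read.tree(text = "((a,b),(c,d));"),
                ape::read.tree(text = "((a,c),(b,d));"),
                ape::read.tree(text = "((a,d),(b,c));"))
  lnls <- vapply(topos, function(tp) {
    tp$edge.length <- rep(0.2, nrow(tp$edge))
    optimize_branch_lengths(tp, aln, gm, seed = 1)$lnl
  }, numeric(1))
  best <- topos[[which.max(lnls)]]
  expect_equal(rf_distance(est, best), 0)
  expect_equal(attr(est, "lnl"), max(lnls), tolerance = 1e-4)
})

test_that("high-signal data recover the generating topology", {
  gm <- gtr_model(rates = c(1.5, 3, 0.8, 1.2, 3.5, 1),
                  freq = c(.3, .2, .2, .3))
  set.seed(31)
  truth <- ape::rtree(6)
  truth$edge.length <- runif(nrow(truth$edge), 0.2, 0.5)
  aln <- simulate_codon_alignment(subst_tree(truth), gm, 2000, seed = 31)
  est <- infer_gene_tree(aln, gm, seed = 2)
  expect_equal(rf_distance(est, truth), 0)
  # restarting from the optimum returns it unchanged
  est2 <- infer_gene_tree(aln, gm, start = est, seed = 2)
  expect_equal(rf_distance(est2, est), 0)
  expect_equal(attr(est2, "n_moves"), 0L)
})

test_that("gene records under near-zero ILS recover the reference everywhere", {
  # species tree with very long internal branches: gene trees == species
  # tree and strong sequence signal
  st <- coal_tree("(((A:12,B:12):8,(C:16,D:16):4):4,(E:20,F:20):4);")
  gt <- simulate_gene_trees(st, 1, seed = 3)[[1]]
  m <- fmutsel0_model(gtr_model(freq = c(.3, .2, .2, .3)),
                      fitness = rnorm(20, sd = 0.5), omega = 0.3)
  aln <- simulate_codon_alignment(scale_to_substitutions(gt, 0.03), m, 900,
                                  seed = 3)
  rec <- build_gene_record(aln, st, outgroup = "E", seed = 1, maxit = 60)
  expect_s3_class(rec, "gene_record")
  expect_equal(rec$distances$rf_est1_ref, 0)
  expect_equal(rec$distances$rf_est2_ref, 0)
  expect_equal(rec$distances$rf_est1_est2, 0)
  expect_error(build_gene_record(aln, st, outgroup = "nope"),
               "missing from locus")
})

test_that("refits store nine fits with the argmax contract", {
  st <- coal_tree("(((A:6,B:6):4,(C:8,D:8):2):2,(E:10,F:10):2);")
  gt <- simulate_gene_trees(st, 1, seed = 5)[[1]]
  m <- fmutsel0_model(gtr_model(freq = c(.3, .2, .2, .3)),
                      fitness = rnorm(20, sd = 0.5), omega = 0.4)
  aln <- simulate_codon_alignment(scale_to_substitutions(gt, 0.05), m, 300,
                                  seed = 5)
  rec <- build_gene_record(aln, st, outgroup = "E", seed = 2, maxit = 50)
  models <- list(gtr = gtr_model(freq = empirical_frequencies(aln)),
                 fmutsel0 = fmutsel0_model(gtr_model(), omega = 0.5),
                 selac = selac_model(psi = 0.02))
  rec <- refit_three_topologies(rec, models, n_starts = 1, seed = 4,
                                maxit = 50)
  expect_named(rec$fits, c("gtr", "fmutsel0", "selac"))
  for (mn in names(models)) {
    lnls <- vapply(rec$fits[[mn]], `[[`, numeric(1), "lnl")
    expect_length(lnls, 3)
    expect_equal(rec$preferred[[mn]], names(which.max(lnls)))
    expect_gte(lnls[rec$preferred[[mn]]], max(lnls))
  }
  # identical topologies refitted twice give identical lnLs
  rec2 <- rec
  rec2$topologies$est2 <- rec2$topologies$est1
  rec2 <- refit_three_topologies(rec2, models["gtr"], n_starts = 1,
                                 seed = 4, maxit = 50)
  expect_equal(rec2$fits$gtr$est1$lnl, rec2$fits$gtr$est2$lnl,
               tolerance = 1e-3)
})

test_that("record building is deterministic under seed", {
  st <- coal_tree("(((A:6,B:6):1,C:7):1,(D:8,E:8):0.5);")
  gt <- simulate_gene_trees(st, 1, seed = 8)[[1]]
  gm <- gtr_model(freq = c(.3, .2, .2, .3))
  aln <- simulate_codon_alignment(scale_to_substitutions(gt, 0.05), gm, 200,
                                  seed = 8)
  aln <- codon_alignment(
    matrix(sample(1:61, 5 * 60, replace = TRUE), 5, 60,
           dimnames = list(st$tip.label, NULL)), "x")
  r1 <- build_gene_record(aln, st, outgroup = "D", seed = 6, maxit = 40)
  r2 <- build_gene_record(aln, st, outgroup = "D", seed = 6, maxit = 40)
  expect_equal(r1$search_lnls, r2$search_lnls)
  expect_equal(ape::write.tree(r1$topologies$est1),
               ape::write.tree(r2$topologies$est1))
})

test_that("per-locus report directories round-trip", {
  st <- coal_tree("(((A:6,B:6):1,C:7):1,(D:8,E:8):0.5);")
  gt <- simulate_gene_trees(st, 1, seed = 9)[[1]]
  gm <- gtr_model(freq = c(.3, .2, .2, .3))
  aln <- simulate_codon_alignment(scale_to_substitutions(gt, 0.1),
                                  fmutsel0_model(gm), 60, seed = 9)
  rec <- build_gene_record(aln, st, outgroup = "D", seed = 3, maxit = 30)
  rec <- refit_three_topologies(rec, list(gtr = gm), n_starts = 1,
                                seed = 3, maxit = 30)
  d <- tempfile()
  paths <- write_gene_record(rec, d)
  expect_true(all(file.exists(paths)))
  j <- jsonlite::read_json(file.path(d, paste0(rec$locus,
                                               "_gtr_est1.json")))
  expect_equal(j$lnl, rec$fits$gtr$est1$lnl)
  row <- read.delim(file.path(d, paste0(rec$locus, "_record.tsv")))
  expect_equal(row$preferred_gtr, rec$preferred[["gtr"]])
  unlink(d, recursive = TRUE)
})
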