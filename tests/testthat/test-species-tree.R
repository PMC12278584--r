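test_that("quartet resolutions match manual reading of small trees", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  qm <- gtdiscord:::.quartet_map(tr)
  expect_equal(unname(qm[["a|b|c|d"]]), 1L)  # ab|cd
  tr2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(unname(gtdiscord:::.quartet_map(tr2)[["a|b|c|d"]]), 2L)
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(unname(gtdiscord:::.quartet_map(star)[["a|b|c|d"]]), 0L)
})

test_that("identical gene trees give the maximal quartet score", {
  st <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  gts <- rep(list(st), 7)
  est <- estimate_species_tree(gts, mode = "exhaustive")
  expect_equal(attr(est, "quartet_score"), 7 * choose(6, 4))
  expect_equal(rf_distance(est, st), 0)
})

test_that("low-ILS simulated gene trees recover the species tree", {
  st <- coal_tree("(((A:6,B:6):2,(C:4,D:4):4):2,(E:8,F:8):2);")
  gts <- simulate_gene_trees(st, 200, seed = 9)
  est <- estimate_species_tree(gts, mode = "exhaustive")
  expect_equal(rf_distance(est, st), 0)
})

test_that("NNI search matches the exhaustive oracle on 6-taxon inputs", {
  for (seed in 1:5) {
    st <- coal_tree("(((A:2,B:2):0.4,(C:1.6,D:1.6):0.8):0.5,(E:2.9,F:2.9):0.5);")
    gts <- simulate_gene_trees(st, 40, seed = 100 + seed)
    ex <- estimate_species_tree(gts, mode = "exhaustive")
    nn <- estimate_species_tree(gts, mode = "nni", seed = seed)
    expect_equal(attr(nn, "quartet_score"), attr(ex, "quartet_score"))
  }
})

test_that("hill-climb handles gene trees with unequal taxon sampling", {
  st <- coal_tree("(((A:6,B:6):2,(C:4,D:4):4):2,((E:6,F:6):1,G:7):3);")
  gts <- simulate_gene_trees(st, 80, seed = 4)
  set.seed(41)
  thinned <- lapply(seq_along(gts), function(i) {
    drop <- sample(st$tip.label, 2)
    keep <- setdiff(st$tip.label, drop)
    ape::keep.tip(gts[[i]], keep)
  })
  est <- estimate_species_tree(thinned, mode = "nni", seed = 2)
  expect_lte(rf_distance(est, st), 2)
  # sparse overlap errors out
  half1 <- ape::keep.tip(st, c("A", "B", "C", "D"))
  half2 <- ape::keep.tip(st, c("E", "F", "G", "A"))
  expect_error(estimate_species_tree(list(half1, half2)), "too sparse")
})

test_that("branch metrics match manual counts on a hand-built case", {
  st <- ape::unroot(ape::read.tree(text = "(((a,b),(c,d)),(e,f));"))
  concordant <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  swapped <- ape::read.tree(text = "(((a,c),(b,d)),(e,f));")
  gts <- c(rep(list(concordant), 3), rep(list(swapped), 2))
  bm <- branch_metrics(st, gts)
  ab_row <- bm[bm$clade == "a,b", ]
  # the a,b|rest branch: 3 of 5 gene trees contain it
  expect_equal(ab_row$gcf, 3 / 5)
  expect_equal(ab_row$split_freq, 3 / 5)
  # the abcd|ef split appears as the e,f edge on the unrooted tree;
  # all 5 gene trees keep it
  abcd_row <- bm[bm$clade == "e,f", ]
  expect_equal(abcd_row$gcf, 1)
  expect_equal(abcd_row$split_freq, 1)
  expect_equal(abcd_row$q1, 1)
  # identical gene trees everywhere: all support metrics 1
  bm_id <- branch_metrics(st, rep(list(concordant), 4))
  expect_true(all(bm_id$q1 == 1))
  expect_true(all(bm_id$gcf == 1))
})

test_that("near-star signal yields quartet support near 1/3", {
  st <- coal_tree("(((A:1,B:1):0.001,C:1.001):1,D:2.001);")
  gts <- simulate_gene_trees(st, 2000, seed = 12)
  bm <- branch_metrics(ape::unroot(st), gts)
  row <- bm[bm$clade %in% c("A,B"), ]
  expect_lt(abs(row$q1 - 1 / 3), 3 * sqrt(2 / 9 / 2000))
})

test_that("coalescent branch length inverts the MSC expectation", {
  expect_equal(coalescent_branch_length(1 / 3), 0)
  expect_equal(coalescent_branch_length(0.2), 0)
  expect_equal(coalescent_branch_length(0.9), -log(0.15), tolerance = 1e-12)
  expect_identical(coalescent_branch_length(1), Inf)
  q <- seq(0.34, 0.999, by = 0.01)
  expect_true(all(diff(coalescent_branch_length(q)) > 0))
  # round trip with the simulator at x = 0.5
  st <- coal_tree("(((A:1,B:1):0.5,C:1.5):1,D:2.5);")
  gts <- simulate_gene_trees(st, 3000, seed = 21)
  bm <- branch_metrics(ape::unroot(st), gts)
  xhat <- bm$coal_len[bm$clade == "A,B"]
  q1 <- bm$q1[bm$clade == "A,B"]
  se_q <- sqrt(q1 * (1 - q1) / 3000)
  band <- abs(coalescent_branch_length(pmin(q1 + 3 * se_q, 1 - 1e-9)) - 0.5)
  expect_lt(abs(xhat - 0.5), max(band,
            abs(coalescent_branch_length(q1 - 3 * se_q) - 0.5)) + 1e-9)
})

test_that("predictive power spans its extremes and compares sanely", {
  st <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  same <- rep(list(st), 10)
  pp <- predictive_power(st, same, seed = 2)
  expect_equal(pp$mean, 1)
  expect_equal(unname(diff(pp$ci)), 0)
  cmp <- compare_predictive_power(pp, pp)
  expect_equal(cmp$p, 1)
  set.seed(6)
  random_gts <- lapply(1:20, function(i) {
    t <- ape::rtree(20); t$tip.label <- paste0("t", 1:20); t
  })
  st_r <- random_gts[[1]]
  others <- random_gts[-1]
  pp_r <- predictive_power(st_r, others, seed = 3)
  expect_lt(pp_r$mean, 0.5)
  expect_error(predictive_power(st, list()), "empty")
})

test_that("control-node counting checks monophyly and validates taxa", {
  st <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  controls <- list(c("a", "b"), c("c", "d"), c("a", "b", "c", "d"),
                   c("e", "f"), c("a", "c"))
  expect_equal(control_nodes_present(st, controls), 4L)
  expect_equal(control_nodes_present(st, list()), 0L)
  expect_error(control_nodes_present(st, list(c("a", "zz"))),
               "unknown taxa")
})

test_that("annotated newick import recovers support values", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1)0.95:0.5,(c:1,d:1)0.40:0.5);", p)
  tr <- import_species_tree(p)
  expect_true(any(abs(na.omit(attr(tr, "support")) - 0.95) < 1e-9))
  writeLines("((a:1,b:1)[pp=0.88]:0.5,(c:1,d:1)[pp=0.2]:0.5);", p)
  tr2 <- import_species_tree(p)
  expect_true(any(abs(na.omit(attr(tr2, "support")) - 0.88) < 1e-9))
  unlink(p)
})
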