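test_that("trimming prunes correctly and validates", {
  cat5 <- ape::read.tree(text = "((((a,b),c),d),e);")
  expect_equal(rf_distance(trim_to_common_taxa(cat5, cat5$tip.label), cat5),
               0)
  trimmed <- trim_to_common_taxa(cat5, c("a", "c", "d", "e"))
  expect_equal(rf_distance(trimmed,
                           ape::read.tree(text = "(((a,c),d),e);")), 0)
  expect_error(trim_to_common_taxa(cat5, c("a", "z", "c", "d")),
               "not in tree")
  expect_error(trim_to_common_taxa(cat5, c("a", "b")), "fewer than 4")
})

test_that("RF distance matches the split-enumeration oracle", {
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(q1, q1), 0)
  expect_equal(rf_distance(q1, q2), 2)
  expect_equal(normalized_rf(q1, q2), 1.0)
  for (seed in 1:6) {
    t1 <- rand_tree(20, seed)
    t2 <- rand_tree(20, seed + 100)
    t2$tip.label <- t1$tip.label
    expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2))
  }
})

test_that("path distance matches the closed example and the BFS oracle", {
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(path_distance(q1, q1), 0)
  expect_equal(path_distance(q1, q2), 2.0)
  for (seed in c(3, 14)) {
    t1 <- rand_tree(15, seed)
    t2 <- rand_tree(15, seed + 50)
    t2$tip.label <- t1$tip.label
    expect_equal(path_distance(t1, t2), oracle_path_distance(t1, t2),
                 tolerance = 1e-10)
    # absolute-sum variant from the same oracle matrices
    d1 <- oracle_path_matrix(t1); d2 <- oracle_path_matrix(t2)
    ord <- rownames(d1)
    expect_equal(path_distance(t1, t2, variant = "absolute"),
                 sum(abs(d1[ord, ord][upper.tri(d1)] -
                         d2[ord, ord][upper.tri(d2)])))
  }
  expect_error(path_distance(q1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets differ")
})

test_that("distances satisfy metric axioms on random tree pairs", {
  set.seed(99)
  for (i in 1:4) {
    ts <- lapply(1:3, function(j) {
      t <- rand_tree(10, i * 10 + j)
      t$tip.label <- paste0("t", 1:10)
      t
    })
    for (f in list(rf_distance, path_distance)) {
      d12 <- f(ts[[1]], ts[[2]]); d21 <- f(ts[[2]], ts[[1]])
      expect_equal(d12, d21)
      expect_equal(f(ts[[1]], ts[[1]]), 0)
      if (d12 == 0)
        expect_equal(oracle_rf(ts[[1]], ts[[2]]), 0)
    }
    # triangle inequality for RF
    expect_lte(rf_distance(ts[[1]], ts[[3]]),
               rf_distance(ts[[1]], ts[[2]]) + rf_distance(ts[[2]], ts[[3]]))
    expect_true(normalized_rf(ts[[1]], ts[[2]]) >= 0 &&
                normalized_rf(ts[[1]], ts[[2]]) <= 1)
  }
})

test_that("discordance ranking labels and agreement flag follow the rules", {
  ref <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  # est1 identical to ref: least discordant under both metrics
  est2 <- ape::read.tree(text = "(((a,c),(b,d)),((e,g),(f,h)));")
  r <- rank_discordance(ref, est2, ref)
  expect_equal(r$least_discordant, "Est.GT.1")
  expect_equal(r$most_discordant, "Est.GT.2")
  expect_true(r$metrics_agree)
  # identical candidates: tie, disqualified
  r2 <- rank_discordance(est2, est2, ref)
  expect_false(r2$metrics_agree)
  expect_equal(r2$least_discordant, "tie/ambiguous")
  # symmetry of the distances stored
  expect_equal(r$rf_est1_est2, rf_distance(est2, ref))
})

test_that("metric disagreement between RF and path rankings is detected", {
  # search random candidate pairs for a case where RF and path orderings
  # conflict; such loci must be disqualified
  found <- FALSE
  for (seed in 1:200) {
    ref <- rand_tree(10, 777)
    e1 <- rand_tree(10, seed); e1$tip.label <- ref$tip.label
    e2 <- rand_tree(10, seed + 1000); e2$tip.label <- ref$tip.label
    rf_order <- sign(rf_distance(e1, ref) - rf_distance(e2, ref))
    pd_order <- sign(path_distance(e1, ref) - path_distance(e2, ref))
    if (rf_order != 0 && pd_order != 0 && rf_order != pd_order) {
      r <- rank_discordance(e1, e2, ref)
      expect_false(r$metrics_agree)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("distance score attains its bounds and matches a hand computation", {
  a <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  far <- ape::read.tree(text = "(((a,h),(g,b)),((e,d),(c,f)));")
  refs <- list(concat = a, min_discord = a, max_discord = far)
  expect_equal(distance_score(a, refs), 1.0)
  refs2 <- list(concat = far, min_discord = far, max_discord = a)
  expect_equal(distance_score(a, refs2), 0.0)
  expect_error(distance_score(a, list(concat = a, min_discord = a,
                                      max_discord = a)), "degenerate")
  # hand computation on a 10-taxon quadruple
  set.seed(5)
  trees <- lapply(1:4, function(i) {
    t <- rand_tree(10, 300 + i); t$tip.label <- paste0("t", 1:10); t
  })
  refs3 <- list(concat = trees[[2]], min_discord = trees[[3]],
                max_discord = trees[[4]])
  all6 <- utils::combn(4, 2)
  rfs <- apply(all6, 2, function(p) rf_distance(trees[[p[1]]], trees[[p[2]]]))
  pds <- apply(all6, 2, function(p) path_distance(trees[[p[1]]],
                                                  trees[[p[2]]]))
  cc <- function(k) ((rfs[k] / max(rfs)) + (pds[k] / max(pds))) / 2
  hand <- ((1 - cc(1)) + (1 - cc(2)) + cc(3)) / 3   # pairs (1,2),(1,3),(1,4)
  expect_equal(distance_score(trees[[1]], refs3), hand, tolerance = 1e-12)
})

test_that("selected-relationships score tallies monophyly correctly", {
  conc <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  maxd <- ape::read.tree(text = "(((a,f),(c,h)),((e,b),(g,d)));")
  refs <- list(concat = conc, min_discord = conc, max_discord = maxd)
  expect_equal(selected_relationships_score(conc, list(), refs), 0L)
  rels <- list(c("a", "b"), c("c", "d"), c("e", "f"))
  expect_equal(selected_relationships_score(conc, rels, refs), 3L)
  # a clade shared with the max-discordance tree scores -1
  test <- ape::read.tree(text = "(((a,f),(c,d)),((e,b),(g,h)));")
  rels2 <- list(c("a", "f"), c("c", "d"))
  expect_equal(selected_relationships_score(test, rels2, refs), 0L)
  expect_error(selected_relationships_score(conc, list(c("a", "zz")), refs),
               "unknown taxa")
})
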