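# minimal hand-built records exercising the filtering/scoring machinery
fake_record <- function(locus, least, agree = TRUE,
                        lnls = c(ref = -10, est1 = -5, est2 = -7)) {
  dist <- data.frame(locus = locus,
                     least_discordant = least,
                     most_discordant = if (agree)
                       setdiff(c("Est.GT.1", "Est.GT.2"), least)
                     else "tie/ambiguous",
                     metrics_agree = agree, stringsAsFactors = FALSE)
  fits <- list(m = lapply(lnls, function(x) list(lnl = x)))
  structure(list(locus = locus, distances = dist, fits = fits,
                 preferred = c(m = names(which.max(lnls)))),
            class = "gene_record")
}

test_that("filtering drops disagreeing loci and balances strata", {
  recs <- c(lapply(1:6, function(i) fake_record(paste0("a", i), "Est.GT.1")),
            lapply(1:6, function(i) fake_record(paste0("b", i), "Est.GT.2")),
            lapply(1:4, function(i) fake_record(paste0("c", i), "Est.GT.1",
                                                agree = FALSE)))
  kept <- filter_and_balance(recs, 8, seed = 3)
  expect_length(kept, 8)
  expect_equal(attr(kept, "n_agree"), 12)
  least <- vapply(kept, function(r) r$distances$least_discordant,
                  character(1))
  expect_equal(sum(least == "Est.GT.1"), 4)
  expect_equal(sum(least == "Est.GT.2"), 4)
  k2 <- filter_and_balance(recs, 8, seed = 3)
  expect_identical(vapply(kept, `[[`, character(1), "locus"),
                   vapply(k2, `[[`, character(1), "locus"))
  # identity selection when everything balances exactly
  balanced <- recs[1:12]
  all12 <- filter_and_balance(balanced, 12, seed = 1)
  expect_length(all12, 12)
  expect_error(filter_and_balance(recs, 14, seed = 1), "insufficient loci")
})

test_that("preference scoring counts argmax hits, zeros for ref and ties", {
  recs <- list(
    fake_record("l1", "Est.GT.1", lnls = c(ref = -10, est1 = -5, est2 = -7)),
    fake_record("l2", "Est.GT.1", lnls = c(ref = -10, est1 = -8, est2 = -2)),
    fake_record("l3", "Est.GT.2", lnls = c(ref = -1, est1 = -8, est2 = -2)),
    fake_record("l4", "Est.GT.2", lnls = c(ref = -9, est1 = -3,
                                           est2 = -3 + 1e-9)))
  sc <- score_preferences(recs, "m")
  # l1 hit; l2 miss; l3 ref wins -> 0; l4 tie -> 0 and logged
  expect_equal(sc$outcomes, c(1L, 0L, 0L, 0L))
  expect_equal(sc$k, 1)
  expect_equal(sc$n, 4)
  expect_equal(sc$ties, "l4")
  all_hit <- list(
    fake_record("h1", "Est.GT.1", lnls = c(ref = -9, est1 = -2, est2 = -5)),
    fake_record("h2", "Est.GT.2", lnls = c(ref = -9, est1 = -5, est2 = -2)))
  expect_equal(score_preferences(all_hit, "m")$k, 2)
})

test_that("sample-SD z-test reproduces the worked proportions", {
  expect_equal(ztest_proportion(19, 38)$z, 0)
  expect_equal(ztest_proportion(19, 38)$p, 1)
  expect_equal(round(ztest_proportion(22, 38)$p, 2), 0.33)
  expect_equal(round(ztest_proportion(25, 38)$p, 2), 0.04)
  expect_warning(zt <- ztest_proportion(10, 10), "degenerate")
  expect_equal(zt$p, 0)
})

test_that("sign and randomization tests agree with closed forms", {
  expect_equal(secondary_tests(rep(1, 10), seed = 1)$sign_p,
               2 * (1 / 2)^10, tolerance = 1e-12)
  half <- secondary_tests(rep(c(0, 1), 10), seed = 1)
  expect_gt(half$sign_p, 0.99)
  expect_gt(half$perm_p, 0.5)
  # randomization p within Monte-Carlo error of the exact binomial p
  outcomes <- c(rep(1, 25), rep(0, 13))
  st <- secondary_tests(outcomes, seed = 5, n_perm = 20000)
  exact <- binom.test(25, 38, 0.5)$p.value
  mc_se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(st$perm_p - exact), 4 * mc_se + 0.01)
})

test_that("KS against the randomized null behaves at the extremes", {
  set.seed(2)
  pooled <- rnorm(200, mean = -500, sd = 30)
  null_like <- ks_vs_randomized_null(
    sample(pooled, 50, TRUE) - sample(pooled, 50, TRUE), pooled, seed = 3)
  expect_gt(null_like$p, 1e-4)
  ident <- ks_vs_randomized_null(rnorm(100), rnorm(4000), n_draws = 4000,
                                 seed = 4)
  shifted <- ks_vs_randomized_null(rnorm(100) + 500, pooled, seed = 5)
  expect_lt(shifted$p, 1e-6)
  expect_error(ks_vs_randomized_null(1, pooled), ">= 2")
  # identical observed and null samples: D = 0, p = 1
  obs <- c(-3, -1, 0, 2, 5)
  res <- ks_vs_randomized_null(obs, c(0, 1), n_draws = 5, seed = 1)
  res$null_sample
  same <- suppressWarnings(stats::ks.test(obs, obs))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
})

test_that("KS p-values are calibrated when the observed sample is null", {
  set.seed(77)
  pooled <- rnorm(300, -1000, 50)
  ps <- vapply(1:200, function(i) {
    obs <- sample(pooled, 40, TRUE) - sample(pooled, 40, TRUE)
    ks_vs_randomized_null(obs, pooled, n_draws = 1000, seed = 1000 + i)$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("regression recovers exact linear structure and is calibrated", {
  x <- c(1, 2, 3, 4, 7, 9)
  r <- regress_dlnl(x, 2 * x, drop_extreme = 0)
  expect_equal(r$fit$slope, 2, tolerance = 1e-10)
  expect_equal(r$fit$r2, 1, tolerance = 1e-10)
  expect_lt(r$fit$p, 1e-8)
  # matches the normal equations on a textbook 5-point set
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  r5 <- regress_dlnl(x5, y5, drop_extreme = 0)
  slope_hand <- sum((x5 - mean(x5)) * (y5 - mean(y5))) /
    sum((x5 - mean(x5))^2)
  expect_equal(r5$fit$slope, slope_hand, tolerance = 1e-12)
  # null calibration
  set.seed(12)
  ps <- vapply(1:500, function(i) {
    regress_dlnl(rnorm(40), rnorm(40), drop_extreme = 0)$fit$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  # outlier refit drops the extreme-x points
  xo <- c(rnorm(30), -20, -21)
  yo <- c(rnorm(30), -40, -42)
  ro <- regress_dlnl(xo, yo, drop_extreme = 2)
  expect_lt(ro$fit$p, 0.01)
  expect_gt(ro$refit$p, 0.001)
  expect_equal(ro$refit$n, 30)
  expect_error(regress_dlnl(rep(1, 5), rnorm(5)), "zero variance")
})
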