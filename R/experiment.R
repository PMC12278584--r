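# The discordance experiment: locus filtering/balancing, binary preference
# scoring, and the test battery (sample-SD z-test, sign test, randomization
# test, KS test against a randomized delta-lnL null, regressions).

#' Filter loci by metric agreement and balance the two candidate families
#'
#' Drops loci whose RF and path rankings disagree (or tie), then samples
#' `n_target/2` loci whose least-discordant candidate is `Est.GT.1` and
#' `n_target/2` with `Est.GT.2`, uniformly at random under `seed`.
#'
#' @param records list of `gene_record`s with filled distance records.
#' @param n_target even number of loci to retain.
#' @param seed integer seed.
#' @return the retained sublist (attribute `"n_agree"`: loci that passed the
#'   agreement filter).
#' @export
filter_and_balance <- function(records, n_target, seed = 1L) {
  stopifnot(n_target %% 2 == 0)
  agree <- vapply(records, function(r) isTRUE(r$distances$metrics_agree),
                  logical(1))
  survivors <- records[agree]
  least <- vapply(survivors, function(r) r$distances$least_discordant,
                  character(1))
  s1 <- which(least == "Est.GT.1")
  s2 <- which(least == "Est.GT.2")
  half <- n_target / 2
  if (length(s1) < half || length(s2) < half)
    stop("insufficient loci per stratum: ", length(s1), " with Est.GT.1 and ",
         length(s2), " with Est.GT.2 least discordant; need ", half, " each")
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  pick <- sort(c(sample(s1, half), sample(s2, half)))
  out <- survivors[pick]
  attr(out, "n_agree") <- length(survivors)
  out
}

#' Binary preference outcomes for one model
#'
#' Outcome 1 when the topology with the best lnL under the model is also the
#' least-discordant estimated gene tree; 0 otherwise (including when the
#' reference topology wins, and when the top two lnLs tie within `tie_tol`
#' -- ties are conservative zeros and are logged in the result).
#'
#' @param records refitted `gene_record`s.
#' @param model model name (must exist in each record's `fits`).
#' @param tie_tol lnL tie tolerance.
#' @return list: `k` (successes), `n` (trials), `outcomes` (0/1 per locus),
#'   `ties` (locus ids scored 0 because of a tie).
#' @export
score_preferences <- function(records, model, tie_tol = 1e-6) {
  outcomes <- integer(length(records))
  ties <- character(0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$fits[[model]])) stop("no fits for model '", model, "'")
    lnls <- vapply(r$fits[[model]], `[[`, numeric(1), "lnl")
    srt <- sort(lnls, decreasing = TRUE)
    least <- switch(r$distances$least_discordant,
                    "Est.GT.1" = "est1", "Est.GT.2" = "est2", NA_character_)
    if (is.na(least)) { outcomes[i] <- 0L; next }
    if (srt[1] - srt[2] < tie_tol) {
      outcomes[i] <- 0L
      ties <- c(ties, r$locus)
      next
    }
    outcomes[i] <- as.integer(names(which.max(lnls)) == least)
  }
  list(k = sum(outcomes), n = length(outcomes), outcomes = outcomes,
       ties = ties)
}

#' One-sample z-test on binary outcomes (sample-SD form)
#'
#' Tests whether the success proportion differs from `p0` using
#' `z = (phat - p0) / (s / sqrt(n))` with `s` the sample standard deviation
#' of the 0/1 outcomes (denominator `n - 1`), and a two-sided normal
#' p-value. This is the mean-comparison z-test convention (as in BSDA's
#' z.test applied to binary data), which reproduces p = 0.33 for 22/38 and
#' p = 0.04 for 25/38.
#'
#' @param k successes, `n` trials, `p0` null proportion.
#' @param n number of trials (>= 2).
#' @param p0 null proportion.
#' @return list `z`, `p` (two-sided), `phat`; with `k` in `{0, n}` the
#'   variance degenerates: `p` is reported as 0 with a warning.
#' @export
ztest_proportion <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, n >= 2)
  phat <- k / n
  s2 <- n * phat * (1 - phat) / (n - 1)
  if (s2 == 0) {
    warning("degenerate variance (all outcomes identical); p reported as 0")
    return(list(z = sign(phat - p0) * Inf, p = 0, phat = phat))
  }
  z <- (phat - p0) / (sqrt(s2) / sqrt(n))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), phat = phat)
}

#' Sign and randomization tests on binary outcomes
#'
#' The sign test is the exact two-sided binomial test at `p0 = 0.5`; the
#' randomization test flips the sign of each centered outcome
#' (`outcome - 0.5`) in `n_perm` permutations and reports the proportion of
#' permutations whose |mean| reaches the observed one.
#'
#' @param outcomes 0/1 vector (length >= 2).
#' @param seed integer seed (randomization test).
#' @param n_perm number of sign-flip permutations.
#' @return list `sign_p`, `perm_p`.
#' @export
secondary_tests <- function(outcomes, seed = 1L, n_perm = 10000L) {
  stopifnot(length(outcomes) >= 2, all(outcomes %in% c(0, 1)))
  n <- length(outcomes)
  sign_p <- stats::binom.test(sum(outcomes), n, p = 0.5)$p.value
  centered <- outcomes - 0.5
  obs <- abs(mean(centered))
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_means <- abs(flips %*% centered) / n
  list(sign_p = sign_p, perm_p = mean(perm_means >= obs - 1e-12))
}

#' Kolmogorov-Smirnov test of observed delta-lnLs against a randomized null
#'
#' The null sample consists of `n_draws` differences of two values drawn
#' independently, with replacement, from the pooled lnL list; the observed
#' delta-lnLs are compared to it with a two-sample KS test (asymptotic
#' p-value).
#'
#' @param observed_dlnl observed per-locus lnL differences (length >= 2).
#' @param pooled_lnls pooled lnL values from all models/trees (nonempty).
#' @param n_draws size of the randomized null sample.
#' @param seed integer seed.
#' @return list `D`, `p`, `null_sample`.
#' @export
ks_vs_randomized_null <- function(observed_dlnl, pooled_lnls,
                                  n_draws = 4000L, seed = 1L) {
  if (length(observed_dlnl) < 2) stop("need >= 2 observed delta-lnLs")
  if (!length(pooled_lnls)) stop("pooled lnL list is empty")
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  a <- sample(pooled_lnls, n_draws, replace = TRUE)
  b <- sample(pooled_lnls, n_draws, replace = TRUE)
  null_sample <- a - b
  ks <- suppressWarnings(stats::ks.test(observed_dlnl, null_sample))
  list(D = unname(ks$statistic), p = ks$p.value, null_sample = null_sample)
}

#' Linear regression of delta-lnL on topological distance
#'
#' Ordinary least squares of `y` on `x` reporting slope, R-squared and the
#' two-sided slope p-value, plus a refit excluding the `drop_extreme` most
#' extreme `x` values (the outlier-robustness check).
#'
#' @param x distances (length >= 3, nonzero variance).
#' @param y delta-lnLs (same length).
#' @param drop_extreme how many extreme-`x` points to drop in the refit.
#' @return list `fit` and `refit`, each with `slope`, `r2`, `p`, `n`.
#' @export
regress_dlnl <- function(x, y, drop_extreme = 2L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("zero variance in x")
  one <- function(xx, yy) {
    fit <- stats::lm(yy ~ xx)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]), r2 = sm$r.squared,
         p = sm$coefficients[2, 4], n = length(xx))
  }
  out <- list(fit = one(x, y))
  if (drop_extreme > 0 && length(x) - drop_extreme >= 3) {
    keep <- order(abs(x - stats::median(x)))[seq_len(length(x) - drop_extreme)]
    if (stats::var(x[keep]) > 0) out$refit <- one(x[keep], y[keep])
  }
  out
}

#' Run the full test battery over refitted records
#'
#' @param records refitted, filtered `gene_record`s.
#' @param models model names to score.
#' @param alpha type-I error threshold recorded alongside.
#' @param seed integer seed for the resampling tests.
#' @return data frame of per-model test results plus attributes
#'   `"per_locus"` (outcome/delta-lnL table) and `"ks"` (KS results per
#'   model).
#' @export
experiment_tests <- function(records, models = c("gtr", "fmutsel0", "selac"),
                             alpha = 0.05, seed = 1L) {
  res <- NULL
  per_locus <- NULL
  ks_list <- list()
  pooled <- unlist(lapply(records, function(r)
    lapply(r$fits, function(fm) c(fm$est1$lnl, fm$est2$lnl))))
  for (mn in models) {
    sc <- score_preferences(records, mn)
    zt <- ztest_proportion(sc$k, sc$n)
    st <- secondary_tests(sc$outcomes, seed = seed)
    dlnl12 <- vapply(records, function(r)
      r$fits[[mn]]$est1$lnl - r$fits[[mn]]$est2$lnl, numeric(1))
    dlnl_lm <- vapply(records, function(r) {
      least <- switch(r$distances$least_discordant,
                      "Est.GT.1" = "est1", "Est.GT.2" = "est2",
                      NA_character_)
      if (is.na(least)) return(NA_real_)
      most <- setdiff(c("est1", "est2"), least)
      r$fits[[mn]][[least]]$lnl - r$fits[[mn]][[most]]$lnl
    }, numeric(1))
    ks12 <- ks_vs_randomized_null(dlnl12, pooled, seed = seed + 7L)
    ks_lm <- ks_vs_randomized_null(dlnl_lm[!is.na(dlnl_lm)], pooled,
                                   seed = seed + 8L)
    ks_list[[mn]] <- list(est1_vs_est2 = ks12[c("D", "p")],
                          least_vs_most = ks_lm[c("D", "p")])
    res <- rbind(res, data.frame(
      model = mn, k = sc$k, n = sc$n, phat = zt$phat, z = zt$z, p = zt$p,
      sign_p = st$sign_p, perm_p = st$perm_p,
      ks12_p = ks12$p, kslm_p = ks_lm$p,
      n_ties = length(sc$ties), significant = zt$p < alpha,
      stringsAsFactors = FALSE))
    per_locus <- rbind(per_locus, data.frame(
      locus = vapply(records, `[[`, character(1), "locus"), model = mn,
      outcome = sc$outcomes, dlnl_est1_est2 = dlnl12,
      dlnl_least_most = dlnl_lm, stringsAsFactors = FALSE))
  }
  attr(res, "per_locus") <- per_locus
  attr(res, "ks") <- ks_list
  res
}
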