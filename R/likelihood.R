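# Phylogenetic likelihood: R-side preparation around the C++ pruning core.

# Prepare reusable likelihood data for a fixed topology: unrooted postorder
# edge structure, per-site-class pattern compression and eigendecompositions.
prepare_likelihood <- function(tree, aln, model) {
  if (model$type == "nucleotide" && aln$type == "codon")
    aln <- nucleotide_view(aln)
  if (model$type == "codon" && aln$type == "nucleotide")
    stop("codon model applied to a nucleotide alignment")
  if (!all(tree$tip.label %in% aln$taxa))
    stop("tree tips absent from alignment: ",
         paste(setdiff(tree$tip.label, aln$taxa), collapse = ", "))
  states <- aln$states[tree$tip.label, , drop = FALSE]
  if (any(colSums(!is.na(states)) == 0))
    stop("alignment column(s) with no resolved states")
  tr <- if (length(tree$tip.label) > 2) ape::unroot(tree) else tree
  tr <- ape::reorder.phylo(tr, "postorder")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  states <- states[tr$tip.label, , drop = FALSE]
  sub_aln <- if (model$type == "codon") codon_alignment(states, aln$id)
             else nucleotide_alignment(states, aln$id)
  classes <- model_site_classes(model, sub_aln)
  for (k in seq_along(classes)) {
    cp <- compress_patterns(states, classes[[k]]$sites)
    tipstates <- cp$states
    tipstates[is.na(tipstates)] <- 0L
    storage.mode(tipstates) <- "integer"
    classes[[k]]$tipstates <- tipstates
    classes[[k]]$weights <- cp$weights
    classes[[k]]$map <- cp$map
  }
  list(tree = tr, edge = tr$edge, blen = tr$edge.length,
       classes = classes, rates = model_rates(model),
       n_sites = ncol(states))
}

.lik_eval <- function(prep, blen, grad = FALSE, site_lnl = FALSE) {
  lnl <- 0
  g <- if (grad) numeric(length(blen)) else NULL
  sl <- if (site_lnl) numeric(prep$n_sites) else NULL
  for (cl in prep$classes) {
    res <- pruning_lnl_cpp(prep$edge, blen, cl$tipstates, cl$weights,
                           cl$decomp$U, cl$decomp$Uinv, cl$decomp$lambda,
                           cl$decomp$pi, prep$rates, grad)
    lnl <- lnl + res$lnl
    if (grad) g <- g + res$gradient
    if (site_lnl) sl[cl$sites] <- res$site_lnl[cl$map]
  }
  list(lnl = lnl, gradient = g, site_lnl = sl)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a fixed tree under a
#' nucleotide (4-state) or codon (61-state) model, with an equal-weight
#' discrete-gamma rate mixture. The tree is treated as unrooted (all models
#' here are reversible); gaps and ambiguities are fully missing states.
#'
#' @param tree `phylo` with branch lengths in expected substitutions per
#'   site/codon.
#' @param aln a [codon_alignment()] (codon alignments are expanded to their
#'   nucleotide view automatically under nucleotide models).
#' @param model a `subst_model`.
#' @param site_lnl if `TRUE`, attach per-site log-likelihoods as attribute
#'   `"site_lnl"`.
#' @return numeric log-likelihood.
#' @export
pruning_lnL <- function(tree, aln, model, site_lnl = FALSE) {
  prep <- prepare_likelihood(tree, aln, model)
  res <- .lik_eval(prep, prep$blen, site_lnl = site_lnl)
  if (!is.finite(res$lnl)) stop("non-finite log-likelihood")
  out <- res$lnl
  if (site_lnl) attr(out, "site_lnl") <- res$site_lnl
  out
}

.BL_MIN <- 1e-8
.BL_MAX <- 20

# One optimization start: bounded L-BFGS-B on log branch lengths (analytic
# gradient), optionally jointly with log omega (numeric gradient component,
# FMutSel0 only).
.fit_once <- function(tree, aln, model, init_blen, init_omega = NULL,
                      maxit = 200, prep = NULL) {
  fit_omega <- !is.null(init_omega)
  if (is.null(prep)) prep <- prepare_likelihood(tree, aln, model)
  nb <- length(prep$blen)
  make_prep <- function(omega) {
    m <- model; m$omega <- omega
    prepare_likelihood(tree, aln, m)
  }
  cur_prep <- prep
  cur_omega <- NA_real_
  get_prep <- function(omega) {
    if (!fit_omega) return(prep)
    if (!identical(omega, cur_omega)) {
      cur_prep <<- make_prep(omega)
      cur_omega <<- omega
    }
    cur_prep
  }
  negll <- function(par) {
    blen <- exp(par[seq_len(nb)])
    p <- get_prep(if (fit_omega) exp(par[nb + 1]) else NULL)
    -.lik_eval(p, blen)$lnl
  }
  neggr <- function(par) {
    blen <- exp(par[seq_len(nb)])
    p <- get_prep(if (fit_omega) exp(par[nb + 1]) else NULL)
    g <- -.lik_eval(p, blen, grad = TRUE)$gradient * blen
    if (fit_omega) {
      h <- 1e-4
      om <- exp(par[nb + 1])
      up <- .lik_eval(make_prep(om * exp(h)), blen)$lnl
      dn <- .lik_eval(make_prep(om * exp(-h)), blen)$lnl
      g <- c(g, -(up - dn) / (2 * h))
    }
    g
  }
  par0 <- log(pmin(pmax(init_blen, .BL_MIN), .BL_MAX))
  lower <- rep(log(.BL_MIN), nb)
  upper <- rep(log(.BL_MAX), nb)
  if (fit_omega) {
    par0 <- c(par0, log(init_omega))
    lower <- c(lower, log(1e-4))
    upper <- c(upper, log(50))
  }
  opt <- stats::optim(par0, negll, neggr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e7))
  blen <- exp(opt$par[seq_len(nb)])
  list(lnl = -opt$value, blen = blen,
       omega = if (fit_omega) exp(opt$par[nb + 1]) else NULL,
       tree = {
         tr <- prep$tree
         tr$edge.length <- blen
         tr
       })
}

#' Multi-start branch-length optimization on a fixed topology
#'
#' Runs `n_starts` bounded quasi-Newton optimizations of branch lengths
#' (optionally jointly with omega for FMutSel0) from jittered initial
#' conditions. The fit is declared converged when two or more starts land
#' within 1 lnL unit of the best (the package-wide convergence rule).
#'
#' @param tree fixed topology (`phylo`); its branch lengths seed start 1.
#' @param aln alignment.
#' @param model `subst_model`.
#' @param n_starts number of independent starts (>= 1).
#' @param seed integer seed controlling the jitter.
#' @param fit_omega also estimate omega (FMutSel0 models only)?
#' @param maxit maximum L-BFGS-B iterations per start.
#' @return object of class `fitted_model`: fields `family`, `lnl`,
#'   `start_lnls`, `converged`, `tree` (optimized branch lengths), `omega`,
#'   `n_starts`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, n_starts = 1L,
                                    seed = 1L, fit_omega = FALSE,
                                    maxit = 200) {
  stopifnot(n_starts >= 1)
  if (fit_omega && !inherits(model, "fmutsel0_model"))
    stop("'fit_omega' is only meaningful for FMutSel0 models")
  # canonical unrooted postorder form so initial lengths align with the
  # optimized edge vector
  prep0 <- prepare_likelihood(tree, aln, model)
  tree <- prep0$tree
  init <- tree$edge.length
  if (is.null(init)) init <- rep(0.1, nrow(tree$edge))
  init[!is.finite(init) | init <= 0] <- 0.05
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  fits <- vector("list", n_starts)
  errors <- character(0)
  for (s in seq_len(n_starts)) {
    b0 <- if (s == 1) init else init * exp(stats::rnorm(length(init), sd = 0.4))
    om0 <- if (fit_omega) {
      if (s == 1) model$omega else model$omega * exp(stats::rnorm(1, sd = 0.4))
    } else NULL
    fits[[s]] <- tryCatch(.fit_once(tree, aln, model, b0, om0,
                                    maxit = maxit,
                                    prep = if (fit_omega) NULL else prep0),
                          error = function(e) e)
    if (inherits(fits[[s]], "error"))
      errors <- c(errors, conditionMessage(fits[[s]]))
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok))
    stop("all optimization starts failed: ",
         paste(unique(errors), collapse = "; "))
  fits <- fits[ok]
  lnls <- vapply(fits, `[[`, numeric(1), "lnl")
  best <- which.max(lnls)
  structure(list(family = class(model)[1], lnl = lnls[best],
                 start_lnls = lnls,
                 converged = sum(lnls >= max(lnls) - 1) >= 2 ||
                   length(lnls) == 1,
                 tree = fits[[best]]$tree, omega = fits[[best]]$omega,
                 n_starts = n_starts),
            class = "fitted_model")
}

#' Staged multi-start fit (4 starts, then 8 more when unconverged)
#'
#' Mirrors the staged protocol: four initial optimization chains; if no two
#' agree to within 1 lnL unit, eight further chains are run and the pooled
#' set is assessed.
#'
#' @inheritParams optimize_branch_lengths
#' @param initial,extra start counts for the two stages.
#' @return a `fitted_model`.
#' @export
fit_staged <- function(tree, aln, model, seed = 1L, fit_omega = FALSE,
                       initial = 4L, extra = 8L, maxit = 200) {
  f1 <- optimize_branch_lengths(tree, aln, model, n_starts = initial,
                                seed = seed, fit_omega = fit_omega,
                                maxit = maxit)
  if (f1$converged && initial > 1) return(f1)
  f2 <- optimize_branch_lengths(tree, aln, model, n_starts = extra,
                                seed = seed + 1000L, fit_omega = fit_omega,
                                maxit = maxit)
  lnls <- c(f1$start_lnls, f2$start_lnls)
  pick <- if (f2$lnl > f1$lnl) f2 else f1
  pick$start_lnls <- lnls
  pick$lnl <- max(lnls)
  pick$converged <- sum(lnls >= max(lnls) - 1) >= 2
  pick$n_starts <- initial + extra
  pick
}

#' Empirical nucleotide frequencies of an alignment
#' @param aln alignment (codon alignments use their nucleotide view).
#' @return length-4 frequency vector (A, C, G, T).
#' @export
empirical_frequencies <- function(aln) {
  nt <- nucleotide_view(aln)
  tab <- tabulate(nt$states[!is.na(nt$states)], 4)
  tab / sum(tab)
}
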