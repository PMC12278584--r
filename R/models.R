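# Substitution-model constructors and rate-matrix builders.
#
# All rate matrices are reversible, have rows summing to zero, and are
# rescaled so the expected rate at stationarity is 1, so branch lengths are
# expected substitutions per site (nucleotide models) or per codon (codon
# models).

.NT <- c("A", "C", "G", "T")

#' GTR+G nucleotide model
#'
#' @param rates six exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (positive; conventionally GT is fixed at 1).
#' @param freq nucleotide frequencies (A, C, G, T), summing to 1.
#' @param alpha gamma shape for among-site rate variation (`Inf` = no
#'   rate variation).
#' @param k number of gamma categories.
#' @param discretization `"median"` (the nucleotide-fit convention here) or
#'   `"mean"` (the codon-fit convention).
#' @return an object of class `gtr_model`.
#' @export
gtr_model <- function(rates = rep(1, 6), freq = rep(0.25, 4),
                      alpha = Inf, k = 4L,
                      discretization = c("median", "mean")) {
  discretization <- match.arg(discretization)
  stopifnot(length(rates) == 6, all(is.finite(rates)), all(rates > 0),
            length(freq) == 4, all(freq > 0))
  if (abs(sum(freq) - 1) > 1e-8) stop("'freq' must sum to 1")
  structure(list(rates = as.numeric(rates), freq = as.numeric(freq),
                 alpha = alpha, k = as.integer(k),
                 discretization = discretization,
                 type = "nucleotide"),
            class = c("gtr_model", "subst_model"))
}

# 4x4 symmetric exchangeability matrix from the 6-vector.
.gtr_R <- function(rates) {
  R <- matrix(0, 4, 4, dimnames = list(.NT, .NT))
  R["A", "C"] <- R["C", "A"] <- rates[1]
  R["A", "G"] <- R["G", "A"] <- rates[2]
  R["A", "T"] <- R["T", "A"] <- rates[3]
  R["C", "G"] <- R["G", "C"] <- rates[4]
  R["C", "T"] <- R["T", "C"] <- rates[5]
  R["G", "T"] <- R["T", "G"] <- rates[6]
  R
}

#' Build a normalized GTR rate matrix
#'
#' @param model a [gtr_model()].
#' @return 4x4 rate matrix with attribute `"pi"` (stationary frequencies).
#' @export
build_gtr_Q <- function(model) {
  R <- .gtr_R(model$rates)
  pi <- model$freq
  Q <- R * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  attr(Q, "pi") <- stats::setNames(pi, .NT)
  Q
}

#' Fixation factor of the mutation-selection framework
#'
#' `h(S) = S / (1 - exp(-S))` with `h(0) = 1`: the relative fixation rate of
#' a mutation with scaled selection coefficient `S`, satisfying
#' `h(S)/h(-S) = exp(S)`.
#'
#' @param S numeric vector of scaled selection coefficients.
#' @return numeric vector of positive factors.
#' @export
fixation_factor <- function(S) {
  out <- ifelse(abs(S) < 1e-8, 1 + S / 2, S / (1 - exp(-S)))
  as.numeric(out)
}

# Mutation-layer codon frequencies: product of position-wise nucleotide
# frequencies, renormalized over the 61 sense codons (F1x4 convention).
.codon_mut_freq <- function(nt_freq) {
  s <- .SENSE
  f <- nt_freq[match(s$p1, .NT)] * nt_freq[match(s$p2, .NT)] *
    nt_freq[match(s$p3, .NT)]
  f / sum(f)
}

# Shared builder: 61x61 mutation-selection codon rate matrix from a GTR
# mutation layer, per-codon log-fitness vector, and omega on nonsynonymous
# changes. Normalized to mean rate 1 at its analytic stationary
# distribution pi_j propto pi_mut_j * exp(fit_j).
.build_mutsel_Q <- function(mut, codon_fitness, omega = 1) {
  stopifnot(length(codon_fitness) == 61, all(is.finite(codon_fitness)),
            is.finite(omega), omega > 0)
  R <- .gtr_R(mut$rates)
  ntf <- mut$freq
  mv <- .codon_moves
  S <- codon_fitness[mv$j] - codon_fitness[mv$i]
  rate <- R[cbind(mv$from, mv$to)] * ntf[mv$to] * fixation_factor(S)
  nonsyn <- .CODON_AA[mv$i] != .CODON_AA[mv$j]
  rate[nonsyn] <- rate[nonsyn] * omega
  Q <- matrix(0, 61, 61, dimnames = list(.SENSE$codon, .SENSE$codon))
  Q[cbind(mv$i, mv$j)] <- rate
  diag(Q) <- -rowSums(Q)
  pi <- .codon_mut_freq(ntf) * exp(codon_fitness)
  pi <- pi / sum(pi)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  attr(Q, "pi") <- stats::setNames(pi, .SENSE$codon)
  Q
}

#' FMutSel0 mutation-selection codon model
#'
#' Amino-acid level scaled fitnesses `F` (one per amino acid, identifiable up
#' to an additive constant; the first is conventionally fixed at 0) over a
#' GTR mutation layer, with `omega` multiplying nonsynonymous rates.
#'
#' @param mut a [gtr_model()] giving the mutation layer (its `alpha`,
#'   `k`, `discretization` are ignored here).
#' @param fitness numeric length-20 vector of amino-acid scaled fitnesses,
#'   indexed by [amino_acids()].
#' @param omega nonsynonymous rate multiplier (> 0).
#' @param alpha,k,discretization gamma rate-variation settings (mean
#'   discretization is the codon-fit convention).
#' @return object of class `fmutsel0_model`.
#' @export
fmutsel0_model <- function(mut = gtr_model(), fitness = rep(0, 20),
                           omega = 1, alpha = Inf, k = 4L,
                           discretization = c("mean", "median")) {
  discretization <- match.arg(discretization)
  stopifnot(inherits(mut, "gtr_model"), length(fitness) == 20,
            all(is.finite(fitness)), is.finite(omega), omega > 0)
  structure(list(mut = mut, fitness = as.numeric(fitness), omega = omega,
                 alpha = alpha, k = as.integer(k),
                 discretization = discretization, type = "codon"),
            class = c("fmutsel0_model", "subst_model"))
}

#' Build the FMutSel0 rate matrix
#'
#' Off-diagonal entries exist only between codons differing at one
#' nucleotide: `q_ij = mu_ij h(F_aa(j) - F_aa(i)) * omega^[nonsyn]`, with
#' `mu_ij` the GTR mutation rate of the changed nucleotide.
#'
#' @param model a [fmutsel0_model()].
#' @return 61x61 rate matrix with attribute `"pi"` equal to the analytic
#'   stationary distribution `pi_mut * exp(F)` (normalized).
#' @export
build_fmutsel0_Q <- function(model) {
  .build_mutsel_Q(model$mut, model$fitness[.CODON_AA], model$omega)
}

#' SelAC-style stabilizing-selection codon model
#'
#' Site fitnesses decline with the weighted Grantham distance to a
#' site-specific optimal amino acid, scaled by a gene-level selection
#' strength `psi` (a proxy for expression level): the log fitness of codon
#' `j` at a site with optimum `a*` is `-psi * G(aa(j), a*)`.
#'
#' @param mut GTR mutation layer.
#' @param weights Grantham property weights (composition, polarity, volume).
#' @param psi gene-level selection scale (>= 0; 0 collapses to the mutation
#'   layer).
#' @param optimal_aa either `"majority"` (per-site optimum = most frequent
#'   amino acid observed at the site), `"ml"` (optimum maximizing the
#'   site likelihood over the 20 candidates), or an explicit integer/character
#'   vector of per-site optima.
#' @param alpha,k,discretization gamma settings.
#' @return object of class `selac_model`.
#' @export
selac_model <- function(mut = gtr_model(),
                        weights = c(1.833, 0.1018, 0.000399),
                        psi = 0.05, optimal_aa = "majority",
                        alpha = Inf, k = 4L,
                        discretization = c("mean", "median")) {
  discretization <- match.arg(discretization)
  stopifnot(inherits(mut, "gtr_model"), psi >= 0, length(weights) == 3)
  structure(list(mut = mut, weights = as.numeric(weights), psi = psi,
                 optimal_aa = optimal_aa, alpha = alpha, k = as.integer(k),
                 discretization = discretization, type = "codon"),
            class = c("selac_model", "subst_model"))
}

#' Build the SelAC-style rate matrix for one optimal amino acid
#'
#' @param model a [selac_model()].
#' @param optimal single amino acid (index 1..20 or one-letter code): the
#'   site's optimum.
#' @return 61x61 rate matrix with attribute `"pi"`.
#' @export
build_selac_Q <- function(model, optimal) {
  if (is.character(optimal)) optimal <- match(optimal, .AA_LEVELS)
  if (is.na(optimal) || optimal < 1 || optimal > 20)
    stop("unknown amino acid code for 'optimal'")
  G <- grantham_distance_matrix(model$weights, scale = FALSE)
  fit <- -model$psi * G[.CODON_AA, optimal]
  .build_mutsel_Q(model$mut, fit, omega = 1)
}

#' Gamma category rates of a model
#' @param model any `subst_model`.
#' @return numeric vector of relative rates (length `k`, or 1 when
#'   `alpha = Inf`).
#' @export
model_rates <- function(model) {
  if (!is.finite(model$alpha)) return(1)
  discrete_gamma(model$alpha, model$k, model$discretization)
}

# Eigen machinery for reversible rate matrices: with B =
# diag(sqrt(pi)) Q diag(1/sqrt(pi)) symmetric, P(t) = U exp(Lambda t) Uinv
# with U = diag(1/sqrt(pi)) V, Uinv = t(V) diag(sqrt(pi)).
rev_eigen <- function(Q) {
  pi <- attr(Q, "pi")
  stopifnot(!is.null(pi))
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sq, Uinv = t(e$vectors) * rep(sq, each = length(sq)),
       lambda = e$values, pi = pi)
}

#' Transition probability matrix
#'
#' @param decomp eigendecomposition from the internal reversible-eigen
#'   helper, or a rate matrix with a `"pi"` attribute.
#' @param t branch length (>= 0).
#' @return stochastic matrix `exp(Qt)`.
#' @export
transition_matrix <- function(decomp, t) {
  if (is.matrix(decomp)) decomp <- rev_eigen(decomp)
  P <- decomp$U %*% (exp(decomp$lambda * t) * decomp$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Site-class structure consumed by the likelihood engine: a list of classes,
# each with a rate matrix (and its eigendecomposition) plus the alignment
# columns it applies to. GTR and FMutSel0 are single-class; SelAC has one
# class per distinct per-site optimal amino acid.
model_site_classes <- function(model, aln) {
  UseMethod("model_site_classes")
}

#' @export
model_site_classes.gtr_model <- function(model, aln) {
  Q <- build_gtr_Q(model)
  list(list(decomp = rev_eigen(Q), sites = seq_len(ncol(aln$states)), Q = Q))
}

#' @export
model_site_classes.fmutsel0_model <- function(model, aln) {
  Q <- build_fmutsel0_Q(model)
  list(list(decomp = rev_eigen(Q), sites = seq_len(ncol(aln$states)), Q = Q))
}

#' @export
model_site_classes.selac_model <- function(model, aln) {
  opt <- site_optima(model, aln)
  classes <- list()
  for (a in sort(unique(opt))) {
    Q <- build_selac_Q(model, a)
    classes[[length(classes) + 1L]] <-
      list(decomp = rev_eigen(Q), sites = which(opt == a), Q = Q)
  }
  classes
}

#' Per-site optimal amino acids for the SelAC-style model
#'
#' `"majority"` takes the most frequent amino acid among the observed (non
#' missing) codons of the column, breaking ties by amino-acid order;
#' `"ml"` scores each candidate optimum by the column's likelihood under the
#' stationary distribution of its matrix and keeps the argmax.
#'
#' @param model a [selac_model()].
#' @param aln a codon alignment (see [codon_alignment()]).
#' @return integer vector (length = columns) of optima indexed by
#'   [amino_acids()].
#' @export
site_optima <- function(model, aln) {
  spec <- model$optimal_aa
  n_site <- ncol(aln$states)
  if (is.numeric(spec) && length(spec) == n_site) return(as.integer(spec))
  if (is.character(spec) && length(spec) == n_site && all(nchar(spec) == 1))
    return(match(spec, .AA_LEVELS))
  if (identical(spec, "majority")) {
    apply(aln$states, 2, function(col) {
      aa <- .CODON_AA[col[!is.na(col)]]
      if (!length(aa)) return(1L)
      tab <- tabulate(aa, 20)
      which.max(tab)
    })
  } else if (identical(spec, "ml")) {
    stat <- vapply(1:20, function(a) {
      pi <- attr(build_selac_Q(model, a), "pi")
      log(pi)
    }, numeric(61))
    apply(aln$states, 2, function(col) {
      obs <- col[!is.na(col)]
      if (!length(obs)) return(1L)
      which.max(colSums(stat[obs, , drop = FALSE]))
    })
  } else stop("invalid 'optimal_aa' specification")
}

#' Stationary distribution of a model
#' @param model a `subst_model`; for SelAC the mixture over site classes is
#'   not defined without data, so `optimal` must be supplied.
#' @param optimal optional optimal amino acid (SelAC only).
#' @return named numeric vector over the model's state space.
#' @export
stationary_distribution <- function(model, optimal = NULL) {
  if (inherits(model, "gtr_model")) return(attr(build_gtr_Q(model), "pi"))
  if (inherits(model, "fmutsel0_model"))
    return(attr(build_fmutsel0_Q(model), "pi"))
  if (inherits(model, "selac_model")) {
    if (is.null(optimal)) stop("SelAC stationary distribution is per-site; supply 'optimal'")
    return(attr(build_selac_Q(model, optimal), "pi"))
  }
  stop("unknown model")
}

#' Empirical codon model from a user-supplied exchangeability file
#'
#' A general reversible 61-state codon model `q_ij = s_ij pi_j` built from
#' a symmetric exchangeability matrix over the sense codons (multi-position
#' changes allowed, as in empirical codon models). No exchangeabilities are
#' bundled: supply a whitespace-delimited 61x61 matrix file (rows/columns
#' in [sense_codons()] order, or labelled with codon names) or the matrix
#' itself. This model can stand in as the second inference family when its
#' published exchangeabilities are available; otherwise the omega-only
#' mutation-selection family is the packaged default.
#'
#' @param exchangeabilities 61x61 symmetric nonnegative matrix or a path
#'   to one.
#' @param freq codon frequencies (length 61, summing to 1); default
#'   uniform.
#' @param alpha,k,discretization gamma settings (mean discretization is
#'   the codon-fit convention).
#' @return object of class `ecm_model`.
#' @export
ecm_model <- function(exchangeabilities, freq = rep(1 / 61, 61),
                      alpha = Inf, k = 4L,
                      discretization = c("mean", "median")) {
  discretization <- match.arg(discretization)
  s <- exchangeabilities
  if (is.character(s)) {
    s <- as.matrix(utils::read.table(s))
    if (!is.null(rownames(s)) && all(rownames(s) %in% .SENSE$codon))
      s <- s[.SENSE$codon, .SENSE$codon]
  }
  s <- unname(as.matrix(s))
  if (!identical(dim(s), c(61L, 61L)))
    stop("exchangeability matrix must be 61x61 over the sense codons")
  if (max(abs(s - t(s))) > 1e-8) stop("exchangeability matrix must be symmetric")
  if (any(s < 0)) stop("exchangeabilities must be nonnegative")
  stopifnot(length(freq) == 61, all(freq > 0))
  if (abs(sum(freq) - 1) > 1e-8) stop("'freq' must sum to 1")
  structure(list(exch = s, freq = as.numeric(freq), alpha = alpha,
                 k = as.integer(k), discretization = discretization,
                 type = "codon"),
            class = c("ecm_model", "subst_model"))
}

#' Build the rate matrix of an empirical codon model
#' @param model an [ecm_model()].
#' @return 61x61 rate matrix with attribute `"pi"`.
#' @export
build_ecm_Q <- function(model) {
  Q <- model$exch * rep(model$freq, each = 61)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi <- model$freq
  Q <- Q / (-sum(pi * diag(Q)))
  dimnames(Q) <- list(.SENSE$codon, .SENSE$codon)
  attr(Q, "pi") <- stats::setNames(pi, .SENSE$codon)
  Q
}

#' @export
model_site_classes.ecm_model <- function(model, aln) {
  Q <- build_ecm_Q(model)
  list(list(decomp = rev_eigen(Q), sites = seq_len(ncol(aln$states)), Q = Q))
}
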