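#' Discrete-gamma relative rates
#'
#' Discretizes a gamma(shape = `alpha`, rate = `alpha`) distribution (mean 1)
#' into `k` equal-probability categories, returning one relative rate per
#' category. Two conventions are supported: `"mean"` uses the conditional
#' mean of each bin (rates average exactly 1 by construction); `"median"`
#' uses the bin medians, rescaled so the rates average 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @param method `"mean"` or `"median"`.
#' @return numeric vector of `k` positive rates with mean 1.
#' @export
discrete_gamma <- function(alpha, k = 4L, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  k <- as.integer(k)
  if (k < 1) stop("'k' must be >= 1")
  if (k == 1L) return(1)
  if (method == "median") {
    p <- (2 * seq_len(k) - 1) / (2 * k)
    r <- stats::qgamma(p, shape = alpha, rate = alpha)
    r * k / sum(r)
  } else {
    # E[X | bin] = k * (F_{alpha+1}(b_{i+1}) - F_{alpha+1}(b_i)) for a
    # gamma(alpha, alpha) variable with equal-probability bin edges b.
    b <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
    edges <- c(0, b, Inf)
    F1 <- stats::pgamma(edges, shape = alpha + 1, rate = alpha)
    k * diff(F1)
  }
}
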