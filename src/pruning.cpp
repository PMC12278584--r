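// Felsenstein pruning over a general reversible substitution model
// (4-state nucleotide or 61-state codon), with a discrete-gamma rate
// mixture and analytic branch-length gradients via a post-order +
// pre-order pass. Per-category partial-likelihood scaling; categories are
// mixed on the log scale.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Edge list must be in ape "postorder" (children before parents).
// tipstates: ntip x npat, 0 = missing else 1..S.
// [[Rcpp::export]]
Rcpp::List pruning_lnl_cpp(const arma::imat& edge,
                           const arma::vec& blen,
                           const arma::imat& tipstates,
                           const arma::vec& weights,
                           const arma::mat& U,
                           const arma::mat& Uinv,
                           const arma::vec& lambda,
                           const arma::vec& pi,
                           const arma::vec& rates,
                           const bool grad) {
  const int S = pi.n_elem;
  const int nedge = edge.n_rows;
  const int npat = tipstates.n_cols;
  const int ntip = tipstates.n_rows;
  const int nnode = edge.max();
  const int root = edge(nedge - 1, 0);
  const int R = rates.n_elem;

  // children edge indices per node
  std::vector<std::vector<int>> child_edges(nnode + 1);
  for (int e = 0; e < nedge; ++e) child_edges[edge(e, 0)].push_back(e);

  // per-pattern mixture accumulation on the log scale
  mat logf(R, npat);              // log f_{r,p}
  mat grat = grad ? mat(nedge, R * npat, fill::zeros) : mat();
  // grat stores (g/f) ratios per edge, category, pattern

  // workspaces reused across categories
  std::vector<mat> down(nnode + 1), M(nedge), Dv(nedge);
  std::vector<rowvec> cum(nnode + 1);

  for (int r = 0; r < R; ++r) {
    // transition (and rate-matrix-times-transition) matrices per edge
    std::vector<mat> P(nedge), QP;
    if (grad) QP.resize(nedge);
    for (int e = 0; e < nedge; ++e) {
      vec el = exp(lambda * (blen(e) * rates(r)));
      P[e] = U * diagmat(el) * Uinv;
      P[e].transform([](double x) { return x < 0 ? 0.0 : x; });
      if (grad) QP[e] = U * diagmat(lambda % el) * Uinv;
    }

    for (int n = ntip + 1; n <= nnode; ++n) {
      down[n] = mat(S, npat, fill::ones);
      cum[n] = rowvec(npat, fill::zeros);
    }

    // post-order pass
    for (int e = 0; e < nedge; ++e) {
      int u = edge(e, 0), v = edge(e, 1);
      if (v <= ntip) {
        mat D(S, npat, fill::zeros);
        for (int p = 0; p < npat; ++p) {
          int s = tipstates(v - 1, p);
          if (s == 0) D.col(p).ones(); else D(s - 1, p) = 1.0;
        }
        Dv[e] = D;
        M[e] = P[e] * D;
      } else {
        // scale the completed child partial before use
        rowvec mx = max(down[v], 0);
        mx.transform([](double x) { return x <= 0 ? 1.0 : x; });
        down[v].each_row() /= mx;
        cum[v] += log(mx);
        Dv[e] = down[v];
        M[e] = P[e] * down[v];
      }
      down[u] %= M[e];
      if (v > ntip) cum[u] += cum[v];
    }

    rowvec froot = pi.t() * down[root];
    for (int p = 0; p < npat; ++p)
      logf(r, p) = std::log(froot(p)) + cum[root](p);

    if (grad) {
      // pre-order pass: out[u] available before its children edges
      std::vector<mat> out(nnode + 1);
      out[root] = mat(S, npat);
      out[root].each_col() = pi;
      for (int e = nedge - 1; e >= 0; --e) {
        int u = edge(e, 0), v = edge(e, 1);
        // B = out[u] * product of sibling messages
        mat B = out[u];
        for (int es : child_edges[u]) if (es != e) B %= M[es];
        // scale B per pattern for numerical range (ratio is scale-free)
        rowvec bmx = max(B, 0);
        bmx.transform([](double x) { return x <= 0 ? 1.0 : x; });
        B.each_row() /= bmx;
        rowvec fe = sum(B % M[e], 0);
        rowvec ge = sum(B % (QP[e] * Dv[e]), 0) * rates(r);
        for (int p = 0; p < npat; ++p) {
          double f = fe(p);
          grat(e, r * npat + p) = f > 0 ? ge(p) / f : 0.0;
        }
        if (v > ntip) {
          out[v] = P[e].t() * B;
          rowvec omx = max(out[v], 0);
          omx.transform([](double x) { return x <= 0 ? 1.0 : x; });
          out[v].each_row() /= omx;
        }
      }
    }
  }

  // mix categories (equal weights) on the log scale
  vec sitelnl(npat);
  vec gradient = grad ? vec(nedge, fill::zeros) : vec();
  for (int p = 0; p < npat; ++p) {
    double m = logf.col(p).max();
    vec w(R);
    double s = 0;
    for (int r = 0; r < R; ++r) { w(r) = std::exp(logf(r, p) - m); s += w(r); }
    sitelnl(p) = m + std::log(s / R);
    if (grad) {
      w /= s; // category posterior weights
      for (int e = 0; e < nedge; ++e) {
        double g = 0;
        for (int r = 0; r < R; ++r) g += w(r) * grat(e, r * npat + p);
        gradient(e) += weights(p) * g;
      }
    }
  }
  double lnl = dot(weights, sitelnl);

  Rcpp::List outl = Rcpp::List::create(Rcpp::Named("lnl") = lnl,
                                       Rcpp::Named("site_lnl") = sitelnl);
  if (grad) outl["gradient"] = gradient;
  return outl;
}
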