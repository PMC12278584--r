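# Anomaly-zone detection: the Degnan-Rosenberg boundary a(x) applied
# cascade-style to contiguous internal-branch pairs, and the four-criteria
# "difficult node" flags.

#' Anomaly-zone boundary function a(x)
#'
#' For an internal species-tree branch of length `x` (coalescent units),
#' a descendant internal branch of length `y < a(x)` places the pair in the
#' anomaly zone (the most probable gene tree differs from the species
#' tree): `a(x) = ln(2/3 + (3 e^{2x} - 2) / (18 (e^{3x} - e^{2x})))`.
#'
#' @param x ancestor branch length(s), strictly positive.
#' @return `a(x)` (may be negative for large `x`, meaning no nonnegative
#'   descendant length is anomalous).
#' @export
a_of_x <- function(x) {
  if (any(x <= 0)) stop("a(x) requires x > 0 (the limit diverges at 0)")
  log(2 / 3 + (3 * exp(2 * x) - 2) / (18 * (exp(3 * x) - exp(2 * x))))
}

#' Root of the anomaly boundary
#'
#' The ancestor length `x*` with `a(x*) = 0`, found by bisection: for
#' `x > x*` no nonnegative descendant branch length is anomalous.
#'
#' @param tol bisection tolerance.
#' @return `x*` (about 0.2655).
#' @export
anomaly_boundary_root <- function(tol = 1e-9) {
  lo <- 0.01; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (a_of_x(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Detect anomaly-zone branch pairs on a species tree
#'
#' Tests every contiguous ancestor/descendant pair of internal branches
#' (terminal branches excluded): the pair is anomalous iff the descendant
#' length `y < a(x)` for ancestor length `x`, both finite and positive.
#' A node is "in the anomaly zone" when it sits between the branches of a
#' flagged pair.
#'
#' @param st rooted binary `phylo`; internal branch lengths in coalescent
#'   units, either directly or supplied via `coal_lengths` (a vector indexed
#'   by edge, e.g. inferred from quartet frequencies with
#'   [coalescent_branch_length()]).
#' @param coal_lengths optional per-edge coalescent lengths replacing
#'   `st$edge.length`.
#' @return list of class `anomaly_report`: `pairs` (data frame: edges,
#'   x, y, a_x, anomalous), `anomalous_nodes` (node ids), `n_anomalous`,
#'   `skipped` (pairs lacking lengths), `length_source`.
#' @export
detect_anomalous_pairs <- function(st, coal_lengths = NULL) {
  src <- if (is.null(coal_lengths)) "tree" else "supplied"
  len <- coal_lengths %||% st$edge.length
  if (is.null(len)) stop("no branch lengths available")
  ntip <- length(st$tip.label)
  internal <- which(st$edge[, 2] > ntip)
  pairs <- NULL
  skipped <- 0L
  for (e in internal) {
    child_node <- st$edge[e, 2]
    child_edges <- which(st$edge[, 1] == child_node & st$edge[, 2] > ntip)
    for (ce in child_edges) {
      x <- len[e]; y <- len[ce]
      if (is.na(x) || is.na(y)) { skipped <- skipped + 1L; next }
      if (!is.finite(x) || !is.finite(y) || x <= 0) {
        skipped <- skipped + 1L; next
      }
      ax <- a_of_x(x)
      pairs <- rbind(pairs, data.frame(
        parent_edge = e, child_edge = ce, node = child_node,
        x = x, y = y, a_x = ax, anomalous = y < ax))
    }
  }
  nodes <- if (is.null(pairs)) integer(0)
           else sort(unique(pairs$node[pairs$anomalous]))
  structure(list(pairs = pairs, anomalous_nodes = nodes,
                 n_anomalous = length(nodes), skipped = skipped,
                 length_source = src),
            class = "anomaly_report")
}

#' Flag difficult nodes by the four-criteria rule
#'
#' A node (internal branch) is difficult when all four hold strictly:
#' coalescent length below `coal_len`, gene concordance factor below `gcf`,
#' split frequency below `split_freq`, and support below `support`.
#' An undefined metric fails its criterion (conservative).
#'
#' @param metrics per-branch data frame from [branch_metrics()] (columns
#'   `coal_len`, `gcf`, `split_freq`, `support`).
#' @param thresholds named list of the four cutoffs (defaults 0.1, 0.1,
#'   0.1, 0.5).
#' @return the metrics frame with a logical `difficult` column and
#'   per-criterion flags.
#' @export
difficult_nodes <- function(metrics,
                            thresholds = list(coal_len = 0.1, gcf = 0.1,
                                              split_freq = 0.1,
                                              support = 0.5)) {
  crit <- function(v, thr) !is.na(v) & v < thr
  metrics$crit_coal <- crit(metrics$coal_len, thresholds$coal_len)
  metrics$crit_gcf <- crit(metrics$gcf, thresholds$gcf)
  metrics$crit_split <- crit(metrics$split_freq, thresholds$split_freq)
  metrics$crit_support <- crit(metrics$support, thresholds$support)
  metrics$difficult <- metrics$crit_coal & metrics$crit_gcf &
    metrics$crit_split & metrics$crit_support
  metrics
}
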