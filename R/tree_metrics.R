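# Topology distances and discordance ranking. RF and path distances are
# computed with phangorn's treedist machinery (the standard implementation
# of both metrics); trees are compared as unrooted topologies and branch
# lengths are ignored throughout.

.check_same_leaves <- function(t1, t2) {
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) || length(only2))
    stop("leaf sets differ; only in tree 1: ",
         paste(only1, collapse = ", "), "; only in tree 2: ",
         paste(only2, collapse = ", "))
}

#' Prune a tree to a taxon subset
#'
#' Drops all tips outside `taxa`, suppressing the resulting degree-2 nodes
#' (their branch lengths are summed).
#'
#' @param tree a `phylo`.
#' @param taxa character vector of labels to keep (a subset of the tree's
#'   tips, at least 4).
#' @return pruned `phylo` (units tag preserved).
#' @export
trim_to_common_taxa <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) < 4) stop("fewer than 4 taxa after trimming")
  .set_units(ape::keep.tip(tree, taxa), tree_units(tree))
}

#' Robinson-Foulds distance
#'
#' Number of bipartitions unique to either tree (unrooted convention).
#'
#' @param t1,t2 trees on the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Normalized Robinson-Foulds distance
#'
#' `RF / (2 (n - 3))` for `n` shared leaves: the proportion of the maximum
#' attainable between binary unrooted trees.
#'
#' @inheritParams rf_distance
#' @return value in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  n <- length(t1$tip.label)
  rf_distance(t1, t2) / (2 * (n - 3))
}

#' Path distance between topologies
#'
#' The Steel-Penny path difference: with `d_T(i,j)` the number of edges on
#' the tip-to-tip path in tree `T`, returns
#' `sqrt(sum_{i<j} (d_t1(i,j) - d_t2(i,j))^2)` (the form computed by
#' phangorn's treedist, which this wraps). `variant = "absolute"` gives the
#' absolute-sum variant `sum |d1 - d2|` instead.
#'
#' @inheritParams rf_distance
#' @param variant `"euclidean"` (default) or `"absolute"`.
#' @return non-negative real.
#' @export
path_distance <- function(t1, t2, variant = c("euclidean", "absolute")) {
  variant <- match.arg(variant)
  .check_same_leaves(t1, t2)
  if (variant == "euclidean")
    return(as.numeric(phangorn::path.dist(ape::unroot(t1), ape::unroot(t2))))
  d1 <- .topo_path_matrix(t1)
  d2 <- .topo_path_matrix(t2)
  ord <- rownames(d1)
  sum(abs(d1[ord, ord][upper.tri(d1)] - d2[ord, ord][upper.tri(d2)]))
}

# tip-to-tip path-length (edge count) matrix of the unrooted topology
.topo_path_matrix <- function(tree) {
  tr <- ape::unroot(tree)
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- stats::cophenetic(tr)
  d[tr$tip.label, tr$tip.label]
}

#' Rank two candidate gene trees by discordance with a reference
#'
#' Computes RF and path distances of both candidates (`Est.GT.1`,
#' `Est.GT.2`) to the reference and to each other, labels the least/most
#' discordant candidate under each metric, and flags whether the two metrics
#' agree. A tie under either metric disqualifies the locus
#' (`metrics_agree = FALSE`): the analysis requires an unambiguous
#' most-discordant tree.
#'
#' @param est1,est2 candidate gene trees (`Est.GT.1`, `Est.GT.2`).
#' @param ref reference species-tree topology, trimmed to the same leaves.
#' @param locus locus id stored in the record.
#' @return a one-row `data.frame` (`distance_record`): distances, labels,
#'   `metrics_agree`.
#' @export
rank_discordance <- function(est1, est2, ref, locus = "locus") {
  rf1 <- rf_distance(est1, ref); rf2 <- rf_distance(est2, ref)
  pd1 <- path_distance(est1, ref); pd2 <- path_distance(est2, ref)
  lab <- c("Est.GT.1", "Est.GT.2")
  rf_most <- if (rf1 == rf2) "tie" else lab[which.max(c(rf1, rf2))]
  pd_most <- if (isTRUE(all.equal(pd1, pd2))) "tie"
             else lab[which.max(c(pd1, pd2))]
  agree <- rf_most != "tie" && pd_most != "tie" && rf_most == pd_most
  most <- if (agree) rf_most else "tie/ambiguous"
  least <- if (agree) setdiff(lab, rf_most) else "tie/ambiguous"
  n <- length(ref$tip.label)
  data.frame(locus = locus,
             rf_est1_ref = rf1, rf_est2_ref = rf2,
             rf_est1_est2 = rf_distance(est1, est2),
             path_est1_ref = pd1, path_est2_ref = pd2,
             path_est1_est2 = path_distance(est1, est2),
             nrf_est1_ref = rf1 / (2 * (n - 3)),
             nrf_est2_ref = rf2 / (2 * (n - 3)),
             least_discordant = least, most_discordant = most,
             metrics_agree = agree,
             stringsAsFactors = FALSE)
}

#' Composite distance score of a test species tree
#'
#' For each reference tree R in `refs`, the combined scaled distance
#' `c(test, R) = (RF/RFmax + path/pathmax) / 2` is computed, with maxima
#' taken over all pairwise comparisons within the evaluated tree set; the
#' score is `((1 - c(Concat)) + (1 - c(MinDiscord)) + c(MaxDiscord)) / 3`,
#' so it is high when the test tree is close to the low-discordance
#' references and far from the maximal-discordance one.
#'
#' @param test species tree under evaluation.
#' @param refs named list with elements `concat`, `min_discord`,
#'   `max_discord` (all on the test tree's leaf set).
#' @return score in `[0, 1]`.
#' @export
distance_score <- function(test, refs) {
  stopifnot(all(c("concat", "min_discord", "max_discord") %in% names(refs)))
  trees <- c(list(test = test), refs[c("concat", "min_discord",
                                       "max_discord")])
  n <- length(trees)
  rf <- matrix(0, n, n); pd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
    pd[i, j] <- pd[j, i] <- path_distance(trees[[i]], trees[[j]])
  }
  rfmax <- max(rf); pdmax <- max(pd)
  if (rfmax == 0 && pdmax == 0)
    stop("degenerate tree set: all pairwise distances are zero, ",
         "distance score undefined")
  cc <- function(j) {
    a <- if (rfmax > 0) rf[1, j] / rfmax else 0
    b <- if (pdmax > 0) pd[1, j] / pdmax else 0
    (a + b) / 2
  }
  ((1 - cc(2)) + (1 - cc(3)) + cc(4)) / 3
}

#' Clade presence on a rooted tree
#' @param tree rooted `phylo`.
#' @param taxa clade definition: a taxon subset.
#' @return `TRUE` if `taxa` form a monophyletic group in `tree` (taxa absent
#'   from the tree are dropped first; fewer than 2 remaining gives `FALSE`).
#' @export
clade_present <- function(tree, taxa) {
  taxa <- intersect(taxa, tree$tip.label)
  if (length(taxa) < 2 || length(taxa) >= length(tree$tip.label))
    return(FALSE)
  ape::is.monophyletic(tree, taxa)
}

#' Selected-relationships score
#'
#' Tallies, over a list of clade definitions: +1 for each relationship
#' present in the test tree and in the concatenation or minimal-discordance
#' reference; -1 for each present in the test tree and in the
#' maximal-discordance reference; relationships absent from the test tree
#' contribute 0.
#'
#' @param test rooted species tree under evaluation.
#' @param relationships list of taxon-subset clade definitions.
#' @param refs named list `concat`, `min_discord`, `max_discord` (rooted).
#' @return integer score.
#' @export
selected_relationships_score <- function(test, relationships, refs) {
  stopifnot(all(c("concat", "min_discord", "max_discord") %in% names(refs)))
  score <- 0L
  for (rel in relationships) {
    unknown <- setdiff(rel, unique(c(test$tip.label, refs$concat$tip.label,
                                     refs$min_discord$tip.label,
                                     refs$max_discord$tip.label)))
    if (length(unknown))
      stop("relationship references unknown taxa: ",
           paste(unknown, collapse = ", "))
    if (!clade_present(test, rel)) next
    if (clade_present(refs$concat, rel) ||
        clade_present(refs$min_discord, rel)) score <- score + 1L
    if (clade_present(refs$max_discord, rel)) score <- score - 1L
  }
  score
}
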