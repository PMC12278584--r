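# Quartet-based coalescent species-tree estimation and the per-branch /
# per-tree evaluation metrics (quartet support, gene concordance factor,
# split frequency, coalescent branch lengths, predictive power, control
# nodes).

# Resolution of the quartet {a,b,c,d} (sorted labels) in a tree, from its
# topological tip-to-tip path matrix: 1 = ab|cd, 2 = ac|bd, 3 = ad|bc,
# 0 = unresolved. The true split is the pairing with the strictly smallest
# path-length sum.
.quartet_res <- function(d, q) {
  s <- c(d[q[1], q[2]] + d[q[3], q[4]],
         d[q[1], q[3]] + d[q[2], q[4]],
         d[q[1], q[4]] + d[q[2], q[3]])
  mn <- min(s)
  if (sum(s == mn) > 1) 0L else which.min(s)
}

# All resolved quartets of a tree as a named integer vector keyed by
# "a|b|c|d" (sorted labels).
.quartet_map <- function(tree) {
  d <- .topo_path_matrix(tree)
  tips <- sort(rownames(d))
  if (length(tips) < 4) return(stats::setNames(integer(0), character(0)))
  combs <- utils::combn(tips, 4)
  keys <- apply(combs, 2, paste, collapse = "|")
  vals <- apply(combs, 2, function(q) .quartet_res(d, q))
  stats::setNames(as.integer(vals), keys)
}

#' Total quartet agreement score of a candidate species tree
#'
#' Each gene tree contributes its resolved induced quartets; the score is
#' the number of (gene tree, quartet) pairs whose resolution matches the
#' candidate's. Missing taxa in a gene tree simply contribute fewer
#' quartets.
#'
#' @param candidate `phylo` on the union taxon set (or a superset).
#' @param gt_maps list of quartet maps from the internal quartet-map helper,
#'   or a list of gene trees (converted automatically).
#' @return integer score.
#' @export
quartet_score <- function(candidate, gt_maps) {
  if (!length(gt_maps)) return(0L)
  if (inherits(gt_maps[[1]], "phylo")) gt_maps <- lapply(gt_maps, .quartet_map)
  cm <- .quartet_map(candidate)
  sum(vapply(gt_maps, function(g) {
    shared <- intersect(names(g), names(cm))
    sum(g[shared] != 0L & g[shared] == cm[shared])
  }, numeric(1)))
}

#' Estimate a species tree by maximizing the quartet agreement score
#'
#' Exhaustive enumeration of all unrooted topologies for up to 8 union
#' taxa (`mode = "exhaustive"`), or NNI hill-climbing (`mode = "nni"`) from
#' a greedy start: the randomly resolved majority consensus when all gene
#' trees share one taxon set, otherwise neighbor joining on the mean
#' topological distance matrix. `mode = "auto"` picks exhaustive for <= 8
#' taxa.
#'
#' @param gene_trees list of >= 2 `phylo` gene trees (taxon sets may
#'   differ).
#' @param mode `"auto"`, `"exhaustive"` or `"nni"`.
#' @param seed integer seed (consensus resolution ties).
#' @return unrooted `phylo` with attribute `"quartet_score"`.
#' @export
estimate_species_tree <- function(gene_trees, mode = c("auto", "exhaustive",
                                                       "nni"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(gene_trees) >= 2)
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (length(taxa) < 4) stop("union taxon set has fewer than 4 taxa")
  # connectivity: every taxon pair must co-occur in some gene tree
  cover <- matrix(FALSE, length(taxa), length(taxa),
                  dimnames = list(taxa, taxa))
  for (g in gene_trees) cover[g$tip.label, g$tip.label] <- TRUE
  if (!all(cover))
    stop("taxon overlap too sparse: some taxon pairs never co-occur")
  gt_maps <- lapply(gene_trees, .quartet_map)
  if (mode == "auto") mode <- if (length(taxa) <= 8) "exhaustive" else "nni"
  if (mode == "exhaustive") {
    if (length(taxa) > 8) stop("exhaustive mode limited to 8 taxa")
    cands <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                tip.label = taxa)
    scores <- vapply(cands, quartet_score, numeric(1), gt_maps = gt_maps)
    best <- cands[[which.max(scores)]]
    attr(best, "quartet_score") <- max(scores)
    return(best)
  }
  # NNI mode
  shared <- all(vapply(gene_trees, function(g)
    setequal(g$tip.label, taxa), logical(1)))
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  start <- if (shared) {
    cons <- ape::consensus(lapply(gene_trees, ape::unroot), p = 0.5)
    ape::multi2di(cons)
  } else {
    dsum <- matrix(0, length(taxa), length(taxa),
                   dimnames = list(taxa, taxa))
    dcnt <- dsum
    for (g in gene_trees) {
      dg <- .topo_path_matrix(g)
      tt <- rownames(dg)
      dsum[tt, tt] <- dsum[tt, tt] + dg
      dcnt[tt, tt] <- dcnt[tt, tt] + 1
    }
    ape::nj(dsum / pmax(dcnt, 1))
  }
  start <- ape::unroot(start)
  start$edge.length <- NULL
  cur <- start
  cur_score <- quartet_score(cur, gt_maps)
  repeat {
    tmp <- cur
    tmp$edge.length <- rep(1, nrow(tmp$edge))
    nbs <- phangorn::nni(tmp)
    sc <- vapply(nbs, quartet_score, numeric(1), gt_maps = gt_maps)
    if (max(sc) > cur_score) {
      cur <- nbs[[which.max(sc)]]
      cur$edge.length <- NULL
      cur_score <- max(sc)
    } else break
  }
  attr(cur, "quartet_score") <- cur_score
  cur
}

# The four tip blocks around an internal edge of an unrooted binary tree:
# list(A, B) below the child node's two subtrees, (C, D) the two remaining
# groups on the parent side.
.edge_blocks <- function(tree) {
  tr <- ape::unroot(tree)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  desc <- vector("list", max(tr$edge))
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  root <- tr$edge[nrow(tr$edge), 1]
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 2]
    if (v <= ntip) next              # internal edges only
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    A <- tr$tip.label[desc[[kids[1]]]]
    B <- tr$tip.label[desc[[kids[2]]]]
    u <- tr$edge[e, 1]
    sibs <- setdiff(tr$edge[tr$edge[, 1] == u, 2], v)
    if (u == root && length(sibs) >= 2) {
      C <- tr$tip.label[desc[[sibs[1]]]]
      D <- tr$tip.label[unlist(desc[sibs[-1]])]
    } else {
      C <- tr$tip.label[desc[[sibs[1]]]]
      D <- setdiff(tr$tip.label, c(A, B, C))
    }
    if (!length(D)) next             # pendant-near-root edge: no 4th block
    out[[length(out) + 1L]] <- list(edge = e, A = A, B = B, C = C, D = D,
                                    length = tr$edge.length[e] %||% NA_real_)
  }
  attr(out, "tree") <- tr
  out
}

# does `tree` (restricted to the relevant taxa) contain the bipartition
# side1 | side2?
.has_restricted_split <- function(tree, side1, side2) {
  s1 <- intersect(side1, tree$tip.label)
  s2 <- intersect(side2, tree$tip.label)
  if (length(s1) < 2 || length(s2) < 2) return(NA)
  sub <- ape::keep.tip(tree, c(s1, s2))
  parts <- ape::prop.part(ape::unroot(sub))
  labs <- attr(parts, "labels")
  target <- sort(match(s1, labs))
  for (p in parts) {
    ps <- sort(p)
    if (identical(ps, target) ||
        identical(ps, sort(setdiff(seq_along(labs), target))))
      return(TRUE)
  }
  # clades of prop.part omit some complements; check complement set too
  FALSE
}

#' Per-branch support metrics from a gene-tree set
#'
#' For every internal branch of the species tree: quartet topology
#' frequencies `q1,q2,q3` (induced quartets with one taxon per adjacent
#' block, counted across gene trees), quartet support (`q1`), the inferred
#' coalescent branch length, the gene concordance factor (fraction of
#' decisive gene trees containing the branch's bipartition restricted to
#' their taxa), and the split frequency (fraction of all gene trees
#' containing the restricted bipartition).
#'
#' @param st binary species tree.
#' @param gene_trees list of gene trees.
#' @param max_quartets cap on sampled quartet combinations per branch per
#'   gene tree (exact enumeration below the cap).
#' @param seed integer seed (only used when subsampling).
#' @return data frame, one row per internal branch, plus attribute
#'   `"blocks"` (the block structure used).
#' @export
branch_metrics <- function(st, gene_trees, max_quartets = 500L, seed = 1L) {
  blocks <- .edge_blocks(st)
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  gt_maps <- lapply(gene_trees, .quartet_map)
  gt_tips <- lapply(gene_trees, `[[`, "tip.label")
  rows <- NULL
  for (b in blocks) {
    counts <- c(0, 0, 0)
    n_decisive <- 0L
    gcf_n <- 0L; gcf_k <- 0L
    n_split <- 0L
    for (gi in seq_along(gene_trees)) {
      A <- intersect(b$A, gt_tips[[gi]]); B <- intersect(b$B, gt_tips[[gi]])
      C <- intersect(b$C, gt_tips[[gi]]); D <- intersect(b$D, gt_tips[[gi]])
      hs <- .has_restricted_split(gene_trees[[gi]], c(b$A, b$B), c(b$C, b$D))
      if (!is.na(hs)) {
        gcf_n <- gcf_n + 1L          # decisive for gCF
        if (hs) { gcf_k <- gcf_k + 1L; n_split <- n_split + 1L }
      }
      if (!length(A) || !length(B) || !length(C) || !length(D)) next
      n_decisive <- n_decisive + 1L
      combs <- expand.grid(a = A, b = B, c = C, d = D,
                           stringsAsFactors = FALSE)
      if (nrow(combs) > max_quartets)
        combs <- combs[sample(nrow(combs), max_quartets), , drop = FALSE]
      gm <- gt_maps[[gi]]
      for (r in seq_len(nrow(combs))) {
        q <- sort(c(combs$a[r], combs$b[r], combs$c[r], combs$d[r]))
        res <- gm[paste(q, collapse = "|")]
        if (is.na(res) || res == 0L) next
        # index (1..3) of the AB|CD resolution in the canonical encoding:
        # q[1]'s partner under AB|CD, located among q[2:4]
        partner <- if (q[1] %in% c(combs$a[r], combs$b[r]))
          setdiff(c(combs$a[r], combs$b[r]), q[1])
        else setdiff(c(combs$c[r], combs$d[r]), q[1])
        concord_idx <- match(partner, q[2:4])
        shift <- (res - concord_idx) %% 3
        counts[shift + 1] <- counts[shift + 1] + 1
      }
    }
    tot <- sum(counts)
    q123 <- if (tot > 0) counts / tot else rep(NA_real_, 3)
    rows <- rbind(rows, data.frame(
      edge = b$edge, q1 = q123[1], q2 = q123[2], q3 = q123[3],
      support = q123[1],
      coal_len = if (is.na(q123[1])) NA_real_
                 else coalescent_branch_length(q123[1]),
      gcf = if (gcf_n > 0) gcf_k / gcf_n else NA_real_,
      split_freq = n_split / length(gene_trees),
      n_decisive = n_decisive,
      clade = paste(sort(c(b$A, b$B)), collapse = ","),
      stringsAsFactors = FALSE))
  }
  attr(rows, "blocks") <- blocks
  rows
}

#' Coalescent branch length from the concordant-quartet frequency
#'
#' Inverts the MSC expectation `q1 = 1 - (2/3) exp(-x)`:
#' `x = -ln(1.5 (1 - q1))` for `q1 > 1/3`, else 0; `q1 = 1` maps to `Inf`.
#'
#' @param q1 concordant quartet frequency in `[0, 1]`.
#' @return coalescent length (>= 0).
#' @export
coalescent_branch_length <- function(q1) {
  stopifnot(all(q1 >= 0 & q1 <= 1))
  ifelse(q1 <= 1 / 3, 0,
         ifelse(q1 == 1, Inf, -log(1.5 * (1 - q1))))
}

#' Predictive power of a species tree against independent gene trees
#'
#' Per gene tree: the fraction of the species tree's internal bipartitions
#' (restricted to that gene tree's taxa, nontrivial after restriction)
#' present in it. Gene trees are resampled with replacement `n_trials`
#' times; the mean of trial means and a 95% percentile interval are
#' reported.
#'
#' @param st species tree.
#' @param independent_gts gene trees not used to build `st`.
#' @param n_trials bootstrap trials.
#' @param seed integer seed.
#' @return list `mean`, `ci` (length 2), `per_gt`, `trial_means`.
#' @export
predictive_power <- function(st, independent_gts, n_trials = 100L,
                             seed = 1L) {
  if (!length(independent_gts)) stop("empty independent gene-tree set")
  blocks <- .edge_blocks(st)
  per_gt <- vapply(independent_gts, function(g) {
    hits <- 0L; def <- 0L
    for (b in blocks) {
      hs <- .has_restricted_split(g, c(b$A, b$B), c(b$C, b$D))
      if (is.na(hs)) next
      def <- def + 1L
      if (hs) hits <- hits + 1L
    }
    if (def == 0) NA_real_ else hits / def
  }, numeric(1))
  vals <- per_gt[!is.na(per_gt)]
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  trial_means <- vapply(seq_len(n_trials), function(i)
    mean(sample(vals, length(vals), replace = TRUE)), numeric(1))
  list(mean = mean(trial_means),
       ci = unname(stats::quantile(trial_means, c(0.025, 0.975))),
       per_gt = per_gt, trial_means = trial_means)
}

#' Compare the predictive power of two species trees
#'
#' Two-sided z-test on the bootstrap trial-mean distributions (sample-SD
#' form).
#'
#' @param pp_a,pp_b results of [predictive_power()].
#' @return list `z`, `p`.
#' @export
compare_predictive_power <- function(pp_a, pp_b) {
  a <- pp_a$trial_means; b <- pp_b$trial_means
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (mean(a) - mean(b)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Count control clades present in a species tree
#'
#' @param st rooted species tree.
#' @param controls list of clade definitions (taxon subsets); unknown taxa
#'   are an error.
#' @return integer count of controls monophyletic in `st`.
#' @export
control_nodes_present <- function(st, controls) {
  for (cl in controls) {
    unknown <- setdiff(cl, st$tip.label)
    if (length(unknown))
      stop("control clade references unknown taxa: ",
           paste(unknown, collapse = ", "))
  }
  sum(vapply(controls, function(cl) clade_present(st, cl), logical(1)))
}

#' Import a species tree with branch-support annotations
#'
#' Reads a newick file whose internal-node support is stored either as node
#' labels (plain numbers, the usual quartet-support form) or as bracketed
#' comments of the form `[pp=0.97]` attached to nodes. Unparseable
#' annotations are preserved as opaque label strings.
#'
#' @param path newick file.
#' @return `phylo` with attribute `"support"`: numeric vector over internal
#'   nodes (`NA` where absent/unparseable).
#' @export
import_species_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # move [pp=x] comments into node labels before parsing
  txt2 <- gsub("\\)\\[pp=([0-9.eE+-]+)\\]", ")\\1", txt)
  txt2 <- gsub("\\[[^]]*\\]", "", txt2)   # drop any other comments
  tr <- ape::read.tree(text = txt2)
  sup <- rep(NA_real_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    parsed <- suppressWarnings(as.numeric(tr$node.label))
    sup <- parsed
  }
  attr(tr, "support") <- sup
  tr
}
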