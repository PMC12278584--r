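# Gene-tree inference (NNI hill-climbing under a fixed model family) and
# the per-locus record that carries the two estimated candidate topologies,
# the trimmed reference topology, their distances and their model refits.

# Pairwise Jukes-Cantor distances on the nucleotide view (NJ starting tree).
.jc_distance_matrix <- function(aln) {
  nt <- nucleotide_view(aln)$states
  n <- nrow(nt)
  d <- matrix(0, n, n, dimnames = list(rownames(nt), rownames(nt)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(nt[i, ]) & !is.na(nt[j, ])
    p <- if (any(ok)) mean(nt[i, ok] != nt[j, ok]) else 0.5
    p <- min(p, 0.74)
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}

#' Infer a gene tree by NNI hill-climbing
#'
#' Starts from a neighbor-joining tree (or a supplied start), re-optimizes
#' branch lengths for every nearest-neighbor-interchange candidate, and
#' accepts the best improving move until no NNI raises the log-likelihood
#' (the "all-NNI" thorough search, without SPR). Deterministic under `seed`.
#'
#' @param aln alignment (>= 4 taxa).
#' @param model `subst_model` family used for scoring.
#' @param start optional starting `phylo`; default: NJ on Jukes-Cantor
#'   distances.
#' @param seed integer seed (branch-length start jitter).
#' @param maxit L-BFGS-B iteration cap per candidate fit.
#' @return unrooted `phylo` with optimized branch lengths; attributes
#'   `"lnl"` (final log-likelihood) and `"n_moves"`.
#' @export
infer_gene_tree <- function(aln, model, start = NULL, seed = 1L,
                            maxit = 100) {
  if (length(aln$taxa) < 4) stop("need >= 4 taxa to infer a gene tree")
  if (is.null(start)) {
    start <- ape::nj(.jc_distance_matrix(aln))
    start$edge.length[start$edge.length < 1e-4] <- 1e-4
  }
  score <- function(tr) {
    tryCatch(optimize_branch_lengths(tr, aln, model, n_starts = 1L,
                                     seed = seed, maxit = maxit),
             error = function(e) stop("likelihood failure on locus '",
                                      aln$id, "': ", conditionMessage(e)))
  }
  cur <- score(start)
  n_moves <- 0L
  repeat {
    nbs <- phangorn::nni(cur$tree)
    fits <- lapply(nbs, function(nb) {
      nb$edge.length <- NULL
      nb2 <- nb
      nb2$edge.length <- rep(mean(cur$tree$edge.length), nrow(nb$edge))
      score(nb2)
    })
    lnls <- vapply(fits, `[[`, numeric(1), "lnl")
    best <- which.max(lnls)
    if (lnls[best] > cur$lnl + 1e-6) {
      cur <- fits[[best]]
      n_moves <- n_moves + 1L
    } else break
  }
  out <- cur$tree
  attr(out, "lnl") <- cur$lnl
  attr(out, "n_moves") <- n_moves
  out
}

#' Build the per-locus gene record
#'
#' Infers the two candidate gene trees (`Est.GT.1` under the nucleotide
#' family, `Est.GT.2` under the codon family), trims the reference species
#' tree to the locus' taxa, roots all three on the designated outgroup, and
#' fills the discordance record.
#'
#' @param aln codon alignment of one locus.
#' @param ref_st reference species-tree topology (contains the locus' taxa).
#' @param outgroup taxon used to root all three topologies.
#' @param family1 nucleotide model family for `Est.GT.1` (default GTR+G4,
#'   median discretization, empirical frequencies).
#' @param family2 codon model family for `Est.GT.2` (default the omega-only
#'   codon family, G4 mean discretization).
#' @param seed integer seed.
#' @param maxit iteration cap per fit during tree search.
#' @return a `gene_record`: fields `locus`, `aln`, `outgroup`, `topologies`
#'   (`ref`, `est1`, `est2`, rooted), `distances`, `search_lnls`.
#' @export
build_gene_record <- function(aln, ref_st, outgroup,
                              family1 = NULL, family2 = NULL, seed = 1L,
                              maxit = 100) {
  if (!outgroup %in% aln$taxa)
    stop("outgroup '", outgroup, "' missing from locus ", aln$id)
  if (!all(aln$taxa %in% ref_st$tip.label))
    stop("reference tree lacks taxa of locus ", aln$id)
  freq <- empirical_frequencies(aln)
  if (is.null(family1))
    family1 <- gtr_model(freq = freq, alpha = 1, k = 4L,
                         discretization = "median")
  if (is.null(family2))
    family2 <- fmutsel0_model(gtr_model(freq = freq), omega = 0.5,
                              alpha = 1, k = 4L, discretization = "mean")
  est1 <- infer_gene_tree(aln, family1, seed = seed, maxit = maxit)
  est2 <- infer_gene_tree(aln, family2, seed = seed + 1L, maxit = maxit)
  ref <- trim_to_common_taxa(ref_st, aln$taxa)
  root_on <- function(tr) {
    tr2 <- ape::root(ape::unroot(tr), outgroup, resolve.root = TRUE)
    tr2
  }
  topo <- list(ref = root_on(ref), est1 = root_on(est1),
               est2 = root_on(est2))
  rec <- list(locus = aln$id, aln = aln, outgroup = outgroup,
              topologies = topo,
              distances = rank_discordance(topo$est1, topo$est2, topo$ref,
                                           locus = aln$id),
              search_lnls = c(est1 = attr(est1, "lnl"),
                              est2 = attr(est2, "lnl")),
              fits = NULL, preferred = NULL)
  class(rec) <- "gene_record"
  rec
}

#' Refit all three topologies under a set of models
#'
#' For each topology (reference, `Est.GT.1`, `Est.GT.2`) and each model,
#' re-optimizes branch lengths on the fixed topology with the staged
#' multi-start protocol and records the fitted models; per model, the
#' preferred topology is the lnL argmax. Non-convergent fits are flagged
#' (field `converged`), not fatal.
#'
#' @param record a `gene_record`.
#' @param models named list of `subst_model`s (e.g. `gtr`, `fmutsel0`,
#'   `selac`).
#' @param n_starts starts per fit (1 = single chain; 4 enables the staged
#'   4-then-8 protocol via [fit_staged()] when `staged = TRUE`).
#' @param seed integer seed.
#' @param staged use the staged protocol instead of a flat `n_starts`?
#' @param maxit iteration cap per fit.
#' @return the record with `fits[[model]][[topology]]` (a `fitted_model`)
#'   and `preferred[[model]]` filled in.
#' @export
refit_three_topologies <- function(record, models, n_starts = 1L, seed = 1L,
                                   staged = FALSE, maxit = 200) {
  stopifnot(inherits(record, "gene_record"), length(names(models)) > 0)
  fits <- list()
  preferred <- character(0)
  for (mn in names(models)) {
    fits[[mn]] <- list()
    for (tn in c("ref", "est1", "est2")) {
      sd <- seed + 17L * match(mn, names(models)) +
        3L * match(tn, c("ref", "est1", "est2"))
      tr <- record$topologies[[tn]]
      fits[[mn]][[tn]] <- if (staged)
        fit_staged(tr, record$aln, models[[mn]], seed = sd, maxit = maxit)
      else optimize_branch_lengths(tr, record$aln, models[[mn]],
                                   n_starts = n_starts, seed = sd,
                                   maxit = maxit)
    }
    lnls <- vapply(fits[[mn]], `[[`, numeric(1), "lnl")
    preferred[mn] <- names(lnls)[which.max(lnls)]
  }
  record$fits <- fits
  record$preferred <- preferred
  record
}

#' Write a per-locus results directory
#'
#' Emits the three topology newicks, one JSON fit report per model and
#' topology (parameters, per-start lnLs, convergence), and a one-row
#' record TSV.
#'
#' @param record a refitted `gene_record`.
#' @param dir output directory (created).
#' @return invisible vector of written paths.
#' @export
write_gene_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tn in names(record$topologies)) {
    p <- file.path(dir, paste0(record$locus, "_", tn, ".nwk"))
    ape::write.tree(record$topologies[[tn]], p)
    paths <- c(paths, p)
  }
  for (mn in names(record$fits)) for (tn in names(record$fits[[mn]])) {
    f <- record$fits[[mn]][[tn]]
    p <- file.path(dir, paste0(record$locus, "_", mn, "_", tn, ".json"))
    jsonlite::write_json(list(
      locus = record$locus, model = mn, topology = tn,
      family = f$family, lnl = f$lnl, start_lnls = f$start_lnls,
      converged = f$converged, omega = f$omega,
      n_starts = f$n_starts,
      branch_lengths = f$tree$edge.length), p, auto_unbox = TRUE,
      digits = NA, null = "null")
    paths <- c(paths, p)
  }
  pref <- as.data.frame(as.list(record$preferred))
  names(pref) <- paste0("preferred_", names(pref))
  row <- cbind(record$distances, pref)
  p <- file.path(dir, paste0(record$locus, "_record.tsv"))
  utils::write.table(row, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
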