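# End-to-end pipeline: simulate -> candidate gene trees -> model refits ->
# preference experiment -> species trees -> evaluation -> anomaly scan.
# Stage outputs are written under the run directory with a manifest, so any
# stage can be resumed.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic dataset.
#' @param n_target loci retained by the balanced experiment (even; at most
#'   `sim$n_loci`).
#' @param alpha predefined type-I error threshold.
#' @param n_starts optimization starts per refit.
#' @param maxit iteration cap per fit.
#' @param gamma_alpha gamma shape used by the fitting models (`Inf` = none).
#' @param selac_psi selection scale of the SelAC-style fitting model.
#' @param st_mode species-tree search mode (see [estimate_species_tree()]).
#' @param out_dir run directory.
#' @param seed master seed; per-stage seeds are derived by fixed offsets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_target = NULL,
                            alpha = 0.05, n_starts = 1L, maxit = 100,
                            gamma_alpha = Inf, selac_psi = 0.02,
                            st_mode = "auto", out_dir = tempfile("gtd_run"),
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), alpha > 0, alpha < 1)
  if (is.null(n_target)) n_target <- sim$n_loci - sim$n_loci %% 2
  structure(list(sim = sim, n_target = n_target, alpha = alpha,
                 n_starts = as.integer(n_starts), maxit = maxit,
                 gamma_alpha = gamma_alpha, selac_psi = selac_psi,
                 st_mode = st_mode, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_path <- function(cfg, stage) file.path(cfg$out_dir,
                                              paste0(stage, ".rds"))

.stage_run <- function(cfg, stage, fun, resume) {
  p <- .stage_path(cfg, stage)
  if (resume && file.exists(p)) return(readRDS(p))
  out <- fun()
  saveRDS(out, p)
  man_path <- file.path(cfg$out_dir, "manifest.json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path) else list()
  man[[stage]] <- list(done = TRUE, time = as.character(Sys.time()))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE)
  out
}

#' Run the full discordance pipeline
#'
#' Executes all stages in order, writing per-stage outputs and a manifest
#' under `cfg$out_dir`; stages already present are reused when
#' `resume = TRUE`.
#'
#' @param cfg a [pipeline_config()].
#' @param resume reuse completed stages found in the run directory?
#' @return invisible list with the run summary (also written as
#'   `summary.json`) and all stage outputs.
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- .stage_run(cfg, "01_simulate", function() {
    s <- simulate_locus_set(cfg$sim)
    write_locus_set(s, file.path(cfg$out_dir, "loci"))
    s
  }, resume)

  records <- .stage_run(cfg, "02_genetrees", function() {
    lapply(seq_along(sim$loci), function(i) {
      lc <- sim$loci[[i]]
      tryCatch(
        build_gene_record(lc$aln, sim$species_tree, sim$outgroup,
                          seed = cfg$seed + 200L + i, maxit = cfg$maxit),
        error = function(e) stop("gene-tree stage failed at locus ",
                                 lc$aln$id, ": ", conditionMessage(e)))
    })
  }, resume)

  refits <- .stage_run(cfg, "03_refit", function() {
    lapply(seq_along(records), function(i) {
      r <- records[[i]]
      freq <- empirical_frequencies(r$aln)
      models <- list(
        gtr = gtr_model(freq = freq, alpha = cfg$gamma_alpha, k = 4L,
                        discretization = "median"),
        fmutsel0 = fmutsel0_model(gtr_model(freq = freq), omega = 0.5,
                                  alpha = cfg$gamma_alpha, k = 4L,
                                  discretization = "mean"),
        selac = selac_model(gtr_model(freq = freq), psi = cfg$selac_psi,
                            optimal_aa = "majority",
                            alpha = cfg$gamma_alpha, k = 4L,
                            discretization = "mean"))
      tryCatch(
        refit_three_topologies(r, models, n_starts = cfg$n_starts,
                               seed = cfg$seed + 300L + i,
                               maxit = cfg$maxit),
        error = function(e) stop("refit stage failed at locus ", r$locus,
                                 ": ", conditionMessage(e)))
    })
  }, resume)

  experiment <- .stage_run(cfg, "04_experiment", function() {
    retained <- filter_and_balance(refits, cfg$n_target,
                                   seed = cfg$seed + 400L)
    tests <- experiment_tests(retained, alpha = cfg$alpha,
                              seed = cfg$seed + 401L)
    regs <- if (length(retained) >= 3) {
      out <- lapply(c("gtr", "fmutsel0", "selac"), function(mn) {
        x <- vapply(retained, function(r) r$distances$rf_est1_est2,
                    numeric(1))
        y <- vapply(retained, function(r)
          r$fits[[mn]]$est1$lnl - r$fits[[mn]]$est2$lnl, numeric(1))
        if (stats::var(x) == 0) NULL else regress_dlnl(x, y)
      })
      names(out) <- c("gtr", "fmutsel0", "selac")
      out
    } else NULL
    list(retained = retained, tests = tests, regressions = regs)
  }, resume)

  st_stage <- .stage_run(cfg, "05_speciestree", function() {
    retained <- experiment$retained
    topo <- function(which) lapply(retained, function(r)
      r$topologies[[which]])
    least <- lapply(retained, function(r)
      r$topologies[[switch(r$distances$least_discordant,
                           "Est.GT.1" = "est1", "Est.GT.2" = "est2")]])
    most <- lapply(retained, function(r)
      r$topologies[[switch(r$distances$most_discordant,
                           "Est.GT.1" = "est1", "Est.GT.2" = "est2")]])
    chosen <- function(mn) lapply(retained, function(r)
      r$topologies[[r$preferred[mn]]])
    sets <- list(est1 = topo("est1"), est2 = topo("est2"),
                 min_discord = least, max_discord = most,
                 fmutsel0 = chosen("fmutsel0"), selac = chosen("selac"))
    sts <- lapply(sets, estimate_species_tree, mode = cfg$st_mode,
                  seed = cfg$seed + 500L)
    for (nm in names(sts))
      ape::write.tree(sts[[nm]], file.path(cfg$out_dir,
                                           paste0("ST_", nm, ".nwk")))
    list(gt_sets = sets, sts = sts)
  }, resume)

  evaluation <- .stage_run(cfg, "06_evaluate", function() {
    sts <- st_stage$sts
    ref <- ape::unroot(sim$species_tree)
    refs <- list(concat = ref, min_discord = sts$min_discord,
                 max_discord = sts$max_discord)
    tab1 <- NULL
    for (nm in c("est1", "est2", "fmutsel0", "selac")) {
      ds <- tryCatch(distance_score(sts[[nm]], refs), error = function(e) NA)
      tab1 <- rbind(tab1, data.frame(st = nm, distance_score = ds))
    }
    gts_true <- lapply(sim$loci, `[[`, "gene_tree")
    tab2 <- lapply(sts[c("est1", "est2", "fmutsel0", "selac")], function(st) {
      bm <- branch_metrics(st, st_stage$gt_sets$est1,
                           seed = cfg$seed + 600L)
      pp <- predictive_power(st, gts_true, seed = cfg$seed + 601L)
      list(mean_support = mean(bm$support, na.rm = TRUE),
           mean_split_freq = mean(bm$split_freq, na.rm = TRUE),
           predictive = pp$mean, predictive_ci = pp$ci, metrics = bm)
    })
    list(tab1 = tab1, tab2 = tab2)
  }, resume)

  anomaly <- .stage_run(cfg, "07_anomaly", function() {
    rep_true <- detect_anomalous_pairs(sim$species_tree)
    bm <- evaluation$tab2$selac$metrics
    diff <- difficult_nodes(bm)
    list(true_st = rep_true, difficult = diff)
  }, resume)

  summary <- list(
    n_loci = cfg$sim$n_loci,
    n_agree = attr(experiment$retained, "n_agree"),
    n_retained = length(experiment$retained),
    preferences = experiment$tests[, c("model", "k", "n", "p")],
    distance_scores = evaluation$tab1,
    n_anomalous_nodes = anomaly$true_st$n_anomalous,
    n_difficult = sum(anomaly$difficult$difficult, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  write_reports(list(experiment = experiment, evaluation = evaluation,
                     anomaly = anomaly), cfg$out_dir)
  invisible(list(summary = summary, sim = sim, records = refits,
                 experiment = experiment, st_stage = st_stage,
                 evaluation = evaluation, anomaly = anomaly))
}

#' Write the tabular reports of a pipeline run
#'
#' Emits the species-tree comparison table, the per-branch metric table,
#' the per-locus experiment table, the distance-histogram data and the
#' regression data as TSV/JSON under `dir`.
#'
#' @param results list with `experiment`, `evaluation`, `anomaly`
#'   components (as produced inside [run_pipeline()]).
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  ex <- results$experiment
  if (!is.null(ex)) {
    wt(ex$tests, "experiment_tests.tsv")
    wt(attr(ex$tests, "per_locus"), "experiment_per_locus.tsv")
    dist_rows <- do.call(rbind, lapply(ex$retained, `[[`, "distances"))
    wt(dist_rows, "distance_histograms.tsv")
    regs <- Filter(Negate(is.null), ex$regressions %||% list())
    if (length(regs)) {
      reg <- do.call(rbind, lapply(names(regs), function(mn) {
        f <- regs[[mn]]$fit
        data.frame(model = mn, slope = f$slope, r2 = f$r2, p = f$p, n = f$n)
      }))
      wt(reg, "regressions.tsv")
    }
  }
  ev <- results$evaluation
  if (!is.null(ev)) {
    wt(ev$tab1, "table1_distance_scores.tsv")
    t2 <- do.call(rbind, lapply(names(ev$tab2), function(nm)
      data.frame(st = nm, mean_support = ev$tab2[[nm]]$mean_support,
                 mean_split_freq = ev$tab2[[nm]]$mean_split_freq,
                 predictive = ev$tab2[[nm]]$predictive)))
    wt(t2, "table2_metrics.tsv")
  }
  an <- results$anomaly
  if (!is.null(an)) {
    if (!is.null(an$true_st$pairs)) wt(an$true_st$pairs, "anomaly_pairs.tsv")
    wt(an$difficult, "difficult_nodes.tsv")
  }
  invisible(paths)
}

# --- preference-test calibration harness -------------------------------

# one random NNI move, applied directly to the edge matrix: pick an
# internal edge (u,v), swap a random child subtree of v with a random
# sibling subtree under u
.one_nni <- function(tree) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  cand <- which(edge[, 2] > ntip)
  if (!length(cand)) return(tree)
  e <- cand[sample.int(length(cand), 1L)]
  u <- edge[e, 1]; v <- edge[e, 2]
  kids_v <- which(edge[, 1] == v)
  sibs <- setdiff(which(edge[, 1] == u), e)
  s_e <- sibs[sample.int(length(sibs), 1L)]
  c_e <- kids_v[sample.int(length(kids_v), 1L)]
  edge[s_e, 1] <- v
  edge[c_e, 1] <- u
  tree$edge <- edge
  tree$edge.length <- NULL
  attr(tree, "order") <- NULL   # edge order changed; force a real reorder
  ape::reorder.phylo(tree, "cladewise")
}

# a pair of candidate topologies, each an independent k-step random NNI
# walk from the truth: identically constructed (hence exchangeable,
# "equally wrong"), and far enough apart that topology distances to a
# reference rarely tie
.nni_walk_pair <- function(tree, k = 3L) {
  walk <- function() {
    cur <- ape::unroot(tree)
    for (i in seq_len(k)) cur <- .one_nni(cur)
    cur
  }
  for (try in 1:10) {
    a <- walk(); b <- walk()
    if (rf_distance(a, b) > 0 &&
        rf_distance(a, tree) > 0 && rf_distance(b, tree) > 0)
      return(list(a, b))
  }
  NULL
}

#' One replicate of the preference-experiment calibration
#'
#' Simulates a small multilocus dataset under the MSC and scores the
#' preference z-test once. Under `design = "null"` the two candidate gene
#' trees are independent k-step random NNI walks from the true gene tree
#' -- identically constructed, hence exchangeable and equally wrong
#' (sequence data simulated on the truth) -- and discordance is ranked
#' against an independent random reference topology, so the ranking
#' carries no information about the data; under
#' `design = "power"` the alignment is instead simulated on whichever
#' candidate is less discordant with the species tree, with strong signal,
#' so the least-discordant gene tree is the true topology.
#'
#' @param design `"null"` or `"power"`.
#' @param n_taxa,n_loci taxa per replicate and target experiment size
#'   (loci retained after the dual-metric agreement filter; a 6x pool of
#'   candidate loci is simulated and filtered, mirroring the
#'   filter-then-select workflow).
#' @param n_sites nucleotide sites per locus.
#' @param seed integer seed.
#' @param maxit reduced-iteration cap for the refits.
#' @return list `k`, `n`, `p` (z-test p-value), `n_kept`.
#' @export
preference_experiment_once <- function(design = c("null", "power"),
                                       n_taxa = 10L, n_loci = 20L,
                                       n_sites = 300L, seed = 1L,
                                       maxit = 40) {
  design <- match.arg(design)
  n_pool <- 6L * n_loci
  cfg <- sim_config(n_taxa = n_taxa, n_loci = n_pool,
                    n_codons_range = c(n_sites, n_sites),
                    short_branch_fraction = 0.5, subst_scale = 0.2,
                    occupancy_range = c(4L, n_taxa), seed = seed)
  st <- simulate_species_tree(cfg)
  gts <- simulate_gene_trees(st, n_pool, seed = seed + 1L)
  model <- gtr_model(freq = c(0.3, 0.2, 0.2, 0.3),
                     rates = c(1.5, 3, 0.8, 1.2, 3.5, 1))
  old <- .seed_set(seed + 2L)
  on.exit(.seed_restore(old), add = TRUE)
  # Under the null the discordance ranking must carry no information about
  # the data: rank each locus against its own independent random reference
  # topology. Ranking against the generating species tree is NOT a null --
  # the MSC couples the species tree's local preference to the true gene
  # tree's branch lengths, so even exchangeable perturbation pairs acquire
  # a real lnL/discordance correlation; and a single shared random
  # reference correlates the outcomes within a replicate.
  random_ref <- function() {
    r <- ape::rtree(length(st$tip.label))
    r$tip.label <- sample(st$tip.label)
    ape::unroot(r)
  }
  outcomes <- integer(0)
  for (i in seq_len(n_pool)) {
    if (length(outcomes) >= n_loci) break
    ref <- if (design == "null") random_ref() else ape::unroot(st)
    gt <- gts[[i]]
    pair <- .nni_walk_pair(gt)
    if (is.null(pair)) next
    estA <- pair[[1]]; estB <- pair[[2]]
    dr <- rank_discordance(estA, estB, ref)
    if (!dr$metrics_agree) next
    least <- switch(dr$least_discordant, "Est.GT.1" = "estA",
                    "Est.GT.2" = "estB")
    truth_tree <- if (design == "null") {
      scale_to_substitutions(gt, cfg$subst_scale)
    } else {
      # strong signal: the least-discordant candidate is the generating
      # topology, with ample, even branch lengths
      tt <- if (least == "estA") estA else estB
      tt$edge.length <- rep(0.3, nrow(tt$edge))
      .set_units(tt, "substitution")
    }
    sim_seed <- seed + 50L + i
    aln <- simulate_codon_alignment(truth_tree, model, n_sites,
                                    seed = sim_seed)
    lnls <- vapply(list(ref = ref, estA = estA, estB = estB), function(tr) {
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      optimize_branch_lengths(tr, aln, model, n_starts = 1L,
                              seed = sim_seed, maxit = maxit)$lnl
    }, numeric(1))
    srt <- sort(lnls, decreasing = TRUE)
    outcomes <- c(outcomes,
                  if (srt[1] - srt[2] < 1e-6) 0L
                  else as.integer(names(which.max(lnls)) == least))
  }
  # a replicate whose pool yields too few retained loci is not a runnable
  # experiment (the z-test's normal approximation needs a working sample)
  if (length(outcomes) < 10)
    return(list(k = NA, n = length(outcomes), p = NA,
                n_kept = length(outcomes)))
  k <- sum(outcomes)
  zt <- if (k == 0 || k == length(outcomes))
    suppressWarnings(ztest_proportion(k, length(outcomes)))
  else ztest_proportion(k, length(outcomes))
  list(k = k, n = length(outcomes), p = zt$p, n_kept = length(outcomes))
}

#' Calibration of the preference z-test over replicate experiments
#'
#' @inheritParams preference_experiment_once
#' @param n_reps replicate experiments.
#' @param alpha rejection threshold.
#' @return list `rejection_rate`, `p_values`, `n_valid`.
#' @export
preference_calibration <- function(n_reps = 300L,
                                   design = c("null", "power"),
                                   n_taxa = 10L, n_loci = 20L,
                                   n_sites = 300L, alpha = 0.05,
                                   seed = 1L, maxit = 40) {
  design <- match.arg(design)
  ps <- vapply(seq_len(n_reps), function(r) {
    res <- preference_experiment_once(design, n_taxa, n_loci, n_sites,
                                      seed = seed + 1009L * r,
                                      maxit = maxit)
    res$p %||% NA_real_
  }, numeric(1))
  ok <- !is.na(ps)
  list(rejection_rate = mean(ps[ok] < alpha), p_values = ps,
       n_valid = sum(ok))
}
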