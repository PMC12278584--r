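# Synthetic-data generation: species trees, multispecies-coalescent (MSC)
# gene trees, codon/nucleotide alignments, and occupancy thinning. Together
# these emulate the structure of a multi-locus protein-coding dataset whose
# gene trees are discordant with the species tree through incomplete
# lineage sorting alone.

#' Simulation configuration
#'
#' Defaults mirror the structure of the empirical dataset the analysis is
#' designed around: 56 taxa, 40 loci of a few hundred codons, per-locus
#' occupancy 34-50 taxa, and a species tree with a sizeable fraction of
#' short (anomaly-zone-candidate) internal branches.
#'
#' @param n_taxa number of species (>= 4).
#' @param n_loci number of loci.
#' @param n_codons_range (min, max) codons per locus.
#' @param birth_rate Yule birth rate shaping the species tree.
#' @param coal_scale multiplier converting tree depth to coalescent units.
#' @param short_branch_fraction proportion of internal branches forced below
#'   0.1 coalescent units.
#' @param subst_scale expected substitutions per codon site per coalescent
#'   unit (> 0).
#' @param occupancy_range (min, max) taxa retained per locus (min >= 4).
#' @param seed integer master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 56L, n_loci = 40L,
                       n_codons_range = c(100L, 500L),
                       birth_rate = 1, coal_scale = 1,
                       short_branch_fraction = 0.2,
                       subst_scale = 0.5,
                       occupancy_range = c(34L, 50L),
                       seed = 1L) {
  stopifnot(n_taxa >= 1, n_loci >= 1, length(n_codons_range) == 2,
            all(n_codons_range >= 1),
            n_codons_range[1] <= n_codons_range[2],
            short_branch_fraction >= 0, short_branch_fraction <= 1,
            subst_scale > 0, length(occupancy_range) == 2,
            occupancy_range[1] >= 4,
            occupancy_range[1] <= occupancy_range[2],
            birth_rate > 0, coal_scale > 0)
  structure(list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
                 n_codons_range = as.integer(n_codons_range),
                 birth_rate = birth_rate, coal_scale = coal_scale,
                 short_branch_fraction = short_branch_fraction,
                 subst_scale = subst_scale,
                 occupancy_range = as.integer(occupancy_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.set_units <- function(tree, units) {
  attr(tree, "units") <- units
  tree
}

#' Branch-length units of a tree
#' @param tree a `phylo`.
#' @return `"coalescent"`, `"substitution"` or `"none"`.
#' @export
tree_units <- function(tree) attr(tree, "units") %||% "none"

#' Simulate a species tree with coalescent-unit branch lengths
#'
#' Draws a Yule tree shape, rescales it to coalescent units, floors internal
#' branches at 0.1, then forces `ceiling(short_branch_fraction * (n_taxa-2))`
#' randomly chosen internal branches below 0.1 to create anomaly-zone
#' candidate regions.
#'
#' @param cfg a [sim_config()].
#' @return rooted binary `phylo`, units `"coalescent"`.
#' @export
simulate_species_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_taxa < 4) stop("n_taxa must be >= 4 to simulate a species tree")
  old <- .seed_set(cfg$seed)
  on.exit(.seed_restore(old), add = TRUE)
  tr <- ape::rphylo(cfg$n_taxa, birth = cfg$birth_rate, death = 0)
  tr$edge.length <- tr$edge.length * cfg$coal_scale
  ntip <- length(tr$tip.label)
  internal <- which(tr$edge[, 2] > ntip)   # n_taxa - 2 of them
  tr$edge.length[internal] <- pmax(tr$edge.length[internal], 0.1)
  n_short <- ceiling(cfg$short_branch_fraction * (cfg$n_taxa - 2))
  if (n_short > 0) {
    pick <- sample(internal, min(n_short, length(internal)))
    tr$edge.length[pick] <- stats::runif(length(pick), 0.01, 0.09)
  }
  .set_units(tr, "coalescent")
}

.preorder_nodes <- function(children, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, nd)
    stack <- c(stack, children[[nd]])
  }
  out
}

#' Simulate multispecies-coalescent gene trees
#'
#' @param species_tree rooted `phylo` with coalescent-unit branch lengths
#'   (units tag `"coalescent"`).
#' @param n_loci number of gene trees.
#' @param seed integer seed.
#' @return list of rooted `phylo` gene trees, branch lengths in coalescent
#'   units.
#' @export
simulate_gene_trees <- function(species_tree, n_loci, seed = 1L) {
  if (is.null(species_tree$edge.length))
    stop("species tree has no branch lengths")
  if (!identical(tree_units(species_tree), "coalescent"))
    stop("species tree branch lengths must be in coalescent units ",
         "(units tag 'coalescent')")
  sp <- ape::reorder.phylo(species_tree, "postorder")
  ntip <- length(sp$tip.label)
  nnode <- max(sp$edge)
  root <- ntip + 1L
  children <- vector("list", nnode)
  for (e in seq_len(nrow(sp$edge)))
    children[[sp$edge[e, 1]]] <- c(children[[sp$edge[e, 1]]], sp$edge[e, 2])
  # depth from root (root = 0, increasing toward tips)
  depth <- numeric(nnode)
  for (nd in .preorder_nodes(children, root)) {
    for (ch in children[[nd]]) {
      e <- which(sp$edge[, 2] == ch)
      depth[ch] <- depth[nd] + sp$edge.length[e]
    }
  }
  parent <- integer(nnode)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  lapply(seq_len(n_loci), function(i) {
    g <- .msc_sample(depth, children, parent, root, ntip)
    tr <- list(edge = g$edge, edge.length = g$len,
               tip.label = sp$tip.label, Nnode = ntip - 1L)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(.renumber_phylo(tr, ntip), "cladewise")
    .set_units(tr, "coalescent")
  })
}

# One MSC draw (one haploid sample per species). Lineage sets flow
# tip-to-root; within the branch above species node nd (length =
# depth[nd] - depth[parent]), k lineages coalesce at total rate k(k-1)/2;
# survivors pass rootward; coalescence is forced above the root
# (rate k(k-1)/2 indefinitely).
.msc_sample <- function(depth, children, parent, root, ntip) {
  n_gene_nodes <- 2L * ntip - 1L
  g_edge <- matrix(0L, n_gene_nodes - 1L, 2)
  g_len <- numeric(n_gene_nodes - 1L)
  n_edge <- 0L
  next_node <- ntip + 1L
  node_depth <- numeric(n_gene_nodes)
  surviving <- vector("list", length(children))

  coalesce_in <- function(lin, d_from, d_to) {
    d <- d_from
    while (length(lin) > 1) {
      k <- length(lin)
      d_new <- d - stats::rexp(1, rate = k * (k - 1) / 2)
      if (d_new < d_to) break
      d <- d_new
      pair <- sample.int(k, 2)
      new <- next_node
      next_node <<- next_node + 1L
      node_depth[new] <<- d
      for (ch in lin[pair]) {
        n_edge <<- n_edge + 1L
        g_edge[n_edge, ] <<- c(new, ch)
        g_len[n_edge] <<- node_depth[ch] - d
      }
      lin <- c(lin[-pair], new)
    }
    lin
  }

  for (nd in rev(.preorder_nodes(children, root))) {
    lin <- if (nd <= ntip) {
      node_depth[nd] <- depth[nd]
      nd
    } else unlist(surviving[children[[nd]]])
    if (nd == root) {
      coalesce_in(lin, depth[nd], -Inf)
    } else {
      surviving[[nd]] <- coalesce_in(lin, depth[nd], depth[parent[nd]])
    }
  }
  list(edge = g_edge[seq_len(n_edge), , drop = FALSE],
       len = g_len[seq_len(n_edge)])
}

# ape requires nodes numbered root = ntip+1 and increasing; renumber an
# arbitrary internal numbering.
.renumber_phylo <- function(tr, ntip) {
  edge <- tr$edge
  internal <- sort(unique(edge[, 1]))
  # root = internal node never appearing as child
  root <- setdiff(internal, edge[, 2])
  ord <- c(root, setdiff(internal, root))
  map <- integer(max(edge))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[ord] <- ntip + seq_along(ord)
  tr$edge <- matrix(map[edge], ncol = 2)
  tr
}

#' Convert coalescent branch lengths to substitution units
#'
#' A single global multiplier: substitutions per codon site per coalescent
#' unit.
#'
#' @param tree `phylo` with coalescent-unit branch lengths.
#' @param subst_scale positive multiplier.
#' @return tree with units tag `"substitution"`.
#' @export
scale_to_substitutions <- function(tree, subst_scale) {
  stopifnot(subst_scale > 0)
  tree$edge.length <- tree$edge.length * subst_scale
  .set_units(tree, "substitution")
}

#' Simulate an alignment along a gene tree
#'
#' Root states are drawn from the model's stationary distribution and
#' evolved along branches by matrix exponentiation of the rate matrix, with
#' per-site discrete-gamma rates when the model carries a finite gamma
#' shape. Codon models emit only sense codons. Nucleotide (GTR) models emit
#' a nucleotide alignment.
#'
#' @param gene_tree rooted `phylo` with substitution-unit branch lengths.
#' @param model a `subst_model` (GTR or FMutSel0; SelAC-style models require
#'   an explicit per-site vector of optimal amino acids).
#' @param n_codons number of codon sites (for nucleotide models: number of
#'   nucleotide sites).
#' @param seed integer seed.
#' @param id locus id.
#' @return a [codon_alignment()] (codon or nucleotide type matching the
#'   model).
#' @export
simulate_codon_alignment <- function(gene_tree, model, n_codons, seed = 1L,
                                     id = "locus") {
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (is.null(gene_tree$edge.length)) stop("gene tree has no branch lengths")
  if (identical(tree_units(gene_tree), "coalescent"))
    stop("gene tree branch lengths are in coalescent units; apply ",
         "scale_to_substitutions() first")
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  if (inherits(model, "selac_model")) {
    spec <- model$optimal_aa
    if (!(is.numeric(spec) || (is.character(spec) && all(nchar(spec) == 1) &&
                               length(spec) > 1)))
      stop("simulation under the SelAC-style model needs explicit per-site ",
           "optimal amino acids")
    opt <- if (is.character(spec)) match(spec, .AA_LEVELS) else as.integer(spec)
    if (length(opt) != n_codons) stop("length of per-site optima != n_codons")
    decomps <- lapply(sort(unique(opt)), function(a)
      rev_eigen(build_selac_Q(model, a)))
    names(decomps) <- as.character(sort(unique(opt)))
    site_class <- match(as.character(opt), names(decomps))
  } else if (inherits(model, "fmutsel0_model")) {
    decomps <- list(rev_eigen(build_fmutsel0_Q(model)))
    site_class <- rep(1L, n_codons)
  } else if (inherits(model, "gtr_model")) {
    decomps <- list(rev_eigen(build_gtr_Q(model)))
    site_class <- rep(1L, n_codons)
  } else stop("unknown model")

  rates <- model_rates(model)
  site_rate <- rates[sample.int(length(rates), n_codons, replace = TRUE)]
  S <- length(decomps[[1]]$pi)

  tr <- ape::reorder.phylo(gene_tree, "cladewise")  # parents before children
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  states <- matrix(NA_integer_, nnode, n_codons)
  root <- tr$edge[1, 1]
  for (k in seq_along(decomps)) {
    idx <- which(site_class == k)
    states[root, idx] <- sample.int(S, length(idx), replace = TRUE,
                                    prob = decomps[[k]]$pi)
  }
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    t_e <- tr$edge.length[e]
    for (k in seq_along(decomps)) {
      idx <- which(site_class == k)
      if (!length(idx)) next
      for (r in unique(site_rate[idx])) {
        sites <- idx[site_rate[idx] == r]
        P <- transition_matrix(decomps[[k]], t_e * r)
        anc <- states[u, sites]
        new <- integer(length(sites))
        for (s in unique(anc)) {
          m <- which(anc == s)
          new[m] <- sample.int(S, length(m), replace = TRUE, prob = P[s, ])
        }
        states[v, sites] <- new
      }
    }
  }
  tipstates <- states[seq_len(ntip), , drop = FALSE]
  rownames(tipstates) <- tr$tip.label
  if (model$type == "codon") codon_alignment(tipstates, id = id)
  else nucleotide_alignment(tipstates, id = id)
}

#' Thin taxa to a target occupancy
#'
#' Retains a uniform-random subset of taxa whose size is drawn uniformly
#' from `occupancy_range`; the designated outgroup is always retained. The
#' tree is pruned to match.
#'
#' @param aln alignment.
#' @param tree matching `phylo`.
#' @param occupancy_range (min, max) taxa to retain (min >= 4).
#' @param outgroup taxon label always kept.
#' @param seed integer seed.
#' @return list with elements `aln` and `tree`.
#' @export
thin_taxa <- function(aln, tree, occupancy_range, outgroup, seed = 1L) {
  stopifnot(length(occupancy_range) == 2, occupancy_range[1] >= 4,
            occupancy_range[1] <= occupancy_range[2])
  if (!outgroup %in% aln$taxa) stop("outgroup '", outgroup,
                                    "' absent from alignment")
  n <- length(aln$taxa)
  if (occupancy_range[2] > n) stop("occupancy bounds exceed taxon count")
  old <- .seed_set(seed)
  on.exit(.seed_restore(old), add = TRUE)
  target <- if (occupancy_range[1] == occupancy_range[2]) occupancy_range[1]
            else sample(seq(occupancy_range[1], occupancy_range[2]), 1)
  others <- setdiff(aln$taxa, outgroup)
  keep <- c(outgroup, sample(others, target - 1))
  keep <- aln$taxa[aln$taxa %in% keep]   # stable order
  new_states <- aln$states[keep, , drop = FALSE]
  new_aln <- if (aln$type == "codon") codon_alignment(new_states, aln$id)
             else nucleotide_alignment(new_states, aln$id)
  units <- tree_units(tree)
  new_tree <- .set_units(ape::keep.tip(tree, keep), units)
  list(aln = new_aln, tree = new_tree)
}

#' Designate an outgroup taxon on a rooted species tree
#'
#' Returns one tip from the smaller side of the root split (ties broken by
#' label order): a lineage that attaches at the root, suitable for rooting
#' every locus.
#'
#' @param tree rooted `phylo`.
#' @return a tip label.
#' @export
designate_outgroup <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k) {
    if (k <= ntip) tree$tip.label[k]
    else tree$tip.label[ape::prop.part(tree)[[k - ntip]]]
  })
  # prop.part indexing: clades of node k are element k - ntip
  sizes <- lengths(sides)
  sort(sides[[which.min(sizes)]])[1]
}

#' Simulate a full locus set
#'
#' Species tree, MSC gene trees, per-locus codon (or nucleotide) alignments
#' and occupancy thinning, driven by a [sim_config()]. Per-stage seeds are
#' derived from `cfg$seed` by fixed offsets.
#'
#' @param cfg a [sim_config()].
#' @param model substitution model used to simulate sequences (default: an
#'   FMutSel0 model with mild purifying selection).
#' @return list with `species_tree`, `outgroup`, and `loci` (per locus:
#'   `aln`, `gene_tree` (coalescent units, thinned), `gene_tree_subst`,
#'   `n_codons`, `seed`).
#' @export
simulate_locus_set <- function(cfg, model = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(model)) {
    old <- .seed_set(cfg$seed + 11L)
    fit <- stats::rnorm(20, sd = 1)
    .seed_restore(old)
    model <- fmutsel0_model(gtr_model(freq = c(0.3, 0.2, 0.2, 0.3)),
                            fitness = fit - fit[1], omega = 0.3)
  }
  st <- simulate_species_tree(cfg)
  outgroup <- designate_outgroup(st)
  gts <- simulate_gene_trees(st, cfg$n_loci, seed = cfg$seed + 1L)
  old <- .seed_set(cfg$seed + 2L)
  n_codons <- sample(seq(cfg$n_codons_range[1], cfg$n_codons_range[2]),
                     cfg$n_loci, replace = TRUE)
  .seed_restore(old)
  loci <- vector("list", cfg$n_loci)
  for (i in seq_len(cfg$n_loci)) {
    gt_sub <- scale_to_substitutions(gts[[i]], cfg$subst_scale)
    aln <- simulate_codon_alignment(gt_sub, model, n_codons[i],
                                    seed = cfg$seed + 100L + i,
                                    id = sprintf("locus%03d", i))
    occ <- pmin(cfg$occupancy_range, cfg$n_taxa)
    th <- thin_taxa(aln, gts[[i]], occ, outgroup,
                    seed = cfg$seed + 5000L + i)
    loci[[i]] <- list(aln = th$aln, gene_tree = th$tree,
                      gene_tree_subst = scale_to_substitutions(
                        th$tree, cfg$subst_scale),
                      n_codons = n_codons[i], seed = cfg$seed + 100L + i)
  }
  list(species_tree = st, outgroup = outgroup, loci = loci)
}

#' Write a simulated locus set to disk
#'
#' One FASTA and one newick per locus plus a manifest TSV (locus id,
#' n_taxa, n_codons, seed) and the species tree.
#'
#' @param sim result of [simulate_locus_set()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_locus_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(sim$species_tree, file.path(dir, "species_tree.nwk"))
  man <- data.frame(locus = character(0), n_taxa = integer(0),
                    n_codons = integer(0), seed = integer(0))
  for (lc in sim$loci) {
    write_codon_fasta(lc$aln, file.path(dir, paste0(lc$aln$id, ".fasta")))
    ape::write.tree(lc$gene_tree, file.path(dir, paste0(lc$aln$id, ".nwk")))
    man <- rbind(man, data.frame(locus = lc$aln$id,
                                 n_taxa = length(lc$aln$taxa),
                                 n_codons = lc$n_codons, seed = lc$seed))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}
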