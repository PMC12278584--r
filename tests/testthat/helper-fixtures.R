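# Shared fixtures and independent oracles used across the suite.

# random binary tree with unit-ish branch lengths, deterministic per seed
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  tr
}

# coalescent-unit tree from newick text
coal_tree <- function(text) {
  tr <- ape::read.tree(text = text)
  attr(tr, "units") <- "coalescent"
  tr
}

subst_tree <- function(tr) {
  attr(tr, "units") <- "substitution"
  tr
}

# --- brute-force oracles -------------------------------------------------

# all nontrivial bipartitions of an unrooted tree as canonical strings
oracle_splits <- function(tree) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  tr <- ape::reorder.phylo(tr, "postorder")
  desc <- vector("list", max(tr$edge))
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge)))
    desc[[tr$edge[e, 1]]] <- c(desc[[tr$edge[e, 1]]], desc[[tr$edge[e, 2]]])
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 2]
    if (v <= ntip) next
    side <- sort(tr$tip.label[desc[[v]]])
    other <- sort(setdiff(tr$tip.label, side))
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

# RF by explicit symmetric difference of split sets
oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# tip-to-tip edge-count matrix by breadth-first search on the tree graph
oracle_path_matrix <- function(tree) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  nn <- max(tr$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(NA_integer_, ntip, ntip,
              dimnames = list(tr$tip.label, tr$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_integer_, nn); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    d[s, ] <- dist[seq_len(ntip)]
  }
  d
}

oracle_path_distance <- function(t1, t2) {
  d1 <- oracle_path_matrix(t1); d2 <- oracle_path_matrix(t2)
  ord <- rownames(d1)
  sqrt(sum((d1[ord, ord][upper.tri(d1)] - d2[ord, ord][upper.tri(d2)])^2))
}

# induced rooted-triple concordance frequency of (a,b | c) in gene trees
triple_freq <- function(gts, a, b, c) {
  mean(vapply(gts, function(g) {
    d <- stats::cophenetic(g)
    d[a, b] < min(d[a, c], d[b, c])
  }, logical(1)))
}

# tiny codon alignment from codon strings
aln_from_codons <- function(seqs, id = "locus") {
  states <- t(vapply(seqs, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    gtdiscord::codon_index(cods)
  }, integer(nchar(seqs[1]) / 3)))
  rownames(states) <- names(seqs)
  gtdiscord::codon_alignment(states, id = id)
}
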