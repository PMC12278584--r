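#' @useDynLib gtdiscord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Standard genetic code, NCBI translation table 1, codons enumerated with
# positions cycling T, C, A, G (third position fastest).
.GC_AA <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.codon_table <- local({
  nt <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  codon <- paste0(g$p1, g$p2, g$p3)
  aa <- strsplit(.GC_AA, "")[[1]]
  data.frame(codon = codon, aa = aa, stringsAsFactors = FALSE)
})

#' Sense-codon state space
#'
#' The 61 sense codons of the standard genetic code (stop codons TAA, TAG,
#' TGA excluded), in a fixed order that defines the state indexing used by
#' every codon rate matrix and likelihood in the package.
#'
#' @return A data frame with columns `codon` (3-letter string), `aa`
#'   (one-letter amino acid) and the three nucleotide positions `p1`,`p2`,`p3`.
#' @export
sense_codons <- function() {
  tab <- .codon_table[.codon_table$aa != "*", , drop = FALSE]
  rownames(tab) <- NULL
  tab$p1 <- substr(tab$codon, 1, 1)
  tab$p2 <- substr(tab$codon, 2, 2)
  tab$p3 <- substr(tab$codon, 3, 3)
  tab
}

.SENSE <- sense_codons()

#' Translate codon strings to sense-state indices
#'
#' @param codons character vector of 3-letter codons (T/C/A/G alphabet;
#'   `U` accepted and converted). Codons containing gaps (`-`), `N` or other
#'   ambiguity codes map to `NA` (treated as missing by the likelihood).
#' @return integer vector of indices into [sense_codons()] (1..61), `NA` for
#'   unresolved codons.
#' @export
codon_index <- function(codons) {
  codons <- chartr("uU", "tT", toupper(codons))
  idx <- match(codons, .SENSE$codon)
  stop_hit <- codons %in% .codon_table$codon[.codon_table$aa == "*"]
  if (any(stop_hit)) {
    stop("stop codon(s) at position(s): ",
         paste(which(stop_hit), collapse = ", "))
  }
  idx
}

# Amino-acid index (1..20, alphabetical one-letter order) per sense codon.
.AA_LEVELS <- sort(unique(.SENSE$aa))
.CODON_AA <- match(.SENSE$aa, .AA_LEVELS)

#' Amino acids in the package's fixed ordering
#' @return character vector of the 20 one-letter codes, in the order used to
#'   index fitness vectors.
#' @export
amino_acids <- function() .AA_LEVELS

# Grantham (1974) side-chain properties: composition c, polarity p,
# volume v; and the weighting constants of the published distance
# D = rho * sqrt(alpha*(dc)^2 + beta*(dp)^2 + gamma*(dv)^2), with rho chosen
# so the mean over amino-acid pairs is 100.
.GRANTHAM <- local({
  p <- data.frame(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE)
  p[match(.AA_LEVELS, p$aa), , drop = FALSE]
})

.GRANTHAM_ALPHA <- 1.833
.GRANTHAM_BETA  <- 0.1018
.GRANTHAM_GAMMA <- 0.000399
.GRANTHAM_RHO   <- 50.723

#' Weighted Grantham distance between amino acids
#'
#' Physico-chemical distance \eqn{G(a,b) = \sqrt{\alpha_c (c_a-c_b)^2 +
#' \alpha_p (p_a-p_b)^2 + \alpha_v (v_a-v_b)^2}} over Grantham's published
#' composition/polarity/volume values. With the default weights and
#' `scale = TRUE` this reproduces Grantham's distance matrix (mean 100).
#' The SelAC-style model calls it with free weights and `scale = FALSE`.
#'
#' @param weights numeric length-3 vector (composition, polarity, volume).
#' @param scale logical; multiply by Grantham's global constant (50.723)?
#' @return 20x20 symmetric matrix indexed by [amino_acids()].
#' @export
grantham_distance_matrix <- function(weights = c(.GRANTHAM_ALPHA,
                                                 .GRANTHAM_BETA,
                                                 .GRANTHAM_GAMMA),
                                     scale = FALSE) {
  stopifnot(length(weights) == 3, all(weights >= 0))
  dc <- outer(.GRANTHAM$c, .GRANTHAM$c, "-")
  dp <- outer(.GRANTHAM$p, .GRANTHAM$p, "-")
  dv <- outer(.GRANTHAM$v, .GRANTHAM$v, "-")
  g <- sqrt(weights[1] * dc^2 + weights[2] * dp^2 + weights[3] * dv^2)
  if (scale) g <- g * .GRANTHAM_RHO
  dimnames(g) <- list(.AA_LEVELS, .AA_LEVELS)
  g
}

# Single-nucleotide neighbourhoods of the sense-codon space, precomputed
# once: for every ordered pair (i, j) of sense codons differing at exactly
# one position, the changed position and the from/to nucleotides.
.NT_LEVELS <- c("A", "C", "G", "T")

.codon_moves <- local({
  s <- .SENSE
  n <- nrow(s)
  pos_mat <- cbind(match(s$p1, .NT_LEVELS),
                   match(s$p2, .NT_LEVELS),
                   match(s$p3, .NT_LEVELS))
  out <- vector("list", 3L)
  for (pos in 1:3) {
    other <- pos_mat[, -pos, drop = FALSE]
    key <- other[, 1] * 10L + other[, 2]
    pairs <- NULL
    for (k in unique(key)) {
      grp <- which(key == k)
      if (length(grp) < 2) next
      cmb <- t(combn(grp, 2))
      pairs <- rbind(pairs, cmb, cmb[, 2:1, drop = FALSE])
    }
    out[[pos]] <- data.frame(i = pairs[, 1], j = pairs[, 2], pos = pos,
                             from = pos_mat[pairs[, 1], pos],
                             to = pos_mat[pairs[, 2], pos])
  }
  do.call(rbind, out)
})
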