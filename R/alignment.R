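# Alignment containers. States are small-integer codes: 1..61 sense codons
# (codon alignments) or 1..4 = A,C,G,T (nucleotide alignments); NA is a
# fully missing state (gap or ambiguity).

#' Codon alignment container
#'
#' @param states integer matrix, taxa x codon sites, entries in 1..61
#'   ([sense_codons()] indexing) or `NA` for missing; rownames are taxon
#'   labels.
#' @param id locus identifier.
#' @return object of class `codon_alignment` (fields `states`, `taxa`, `id`,
#'   `type`).
#' @export
codon_alignment <- function(states, id = "locus") {
  stopifnot(is.matrix(states), !is.null(rownames(states)))
  ok <- is.na(states) | (states >= 1 & states <= 61)
  if (!all(ok)) stop("codon states must be NA or in 1..61")
  structure(list(states = states, taxa = rownames(states), id = id,
                 type = "codon"),
            class = "codon_alignment")
}

#' Nucleotide alignment container
#' @param states integer matrix (1..4 = A,C,G,T or `NA`), rownames = taxa.
#' @param id locus identifier.
#' @return object of class `codon_alignment` with `type = "nucleotide"`
#'   (shared container).
#' @export
nucleotide_alignment <- function(states, id = "locus") {
  stopifnot(is.matrix(states), !is.null(rownames(states)))
  ok <- is.na(states) | (states >= 1 & states <= 4)
  if (!all(ok)) stop("nucleotide states must be NA or in 1..4")
  structure(list(states = states, taxa = rownames(states), id = id,
                 type = "nucleotide"),
            class = "codon_alignment")
}

#' Nucleotide view of a codon alignment
#'
#' Expands each codon column into its three nucleotide columns (the view the
#' GTR+G fits use). Missing codons expand to three missing nucleotides.
#'
#' @param aln a [codon_alignment()].
#' @return a nucleotide alignment.
#' @export
nucleotide_view <- function(aln) {
  if (aln$type == "nucleotide") return(aln)
  st <- aln$states
  n <- nrow(st); L <- ncol(st)
  p1 <- match(.SENSE$p1, .NT_LEVELS)
  p2 <- match(.SENSE$p2, .NT_LEVELS)
  p3 <- match(.SENSE$p3, .NT_LEVELS)
  out <- matrix(NA_integer_, n, 3L * L, dimnames = list(rownames(st), NULL))
  out[, seq(1, 3 * L, 3)] <- matrix(p1[st], n, L)
  out[, seq(2, 3 * L, 3)] <- matrix(p2[st], n, L)
  out[, seq(3, 3 * L, 3)] <- matrix(p3[st], n, L)
  nucleotide_alignment(out, id = aln$id)
}

#' Read a codon-aligned FASTA file
#'
#' Enforces codon frame (alignment length divisible by 3) and rejects stop
#' codons with a position report. Gaps (`-`) and ambiguity codes become
#' missing codons.
#'
#' @param path FASTA file path.
#' @param id locus id (defaults to the file name).
#' @return a [codon_alignment()].
#' @export
read_codon_fasta <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  chr <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  if (ncol(chr) %% 3 != 0)
    stop("alignment length ", ncol(chr), " is not divisible by 3")
  L <- ncol(chr) / 3
  states <- matrix(NA_integer_, nrow(chr), L,
                   dimnames = list(names(dna), NULL))
  stop_codons <- .codon_table$codon[.codon_table$aa == "*"]
  for (i in seq_len(nrow(chr))) {
    cod <- paste0(chr[i, seq(1, 3 * L, 3)], chr[i, seq(2, 3 * L, 3)],
                  chr[i, seq(3, 3 * L, 3)])
    bad <- which(cod %in% stop_codons)
    if (length(bad))
      stop("stop codon in ", names(dna)[i], " at codon position(s) ",
           paste(bad, collapse = ", "))
    states[i, ] <- match(cod, .SENSE$codon)
  }
  codon_alignment(states, id = id)
}

#' Write a codon alignment as FASTA
#'
#' @param aln a [codon_alignment()] (codon or nucleotide type).
#' @param path output path. Missing states are written as `---` (codon) or
#'   `-` (nucleotide).
#' @export
write_codon_fasta <- function(aln, path) {
  if (aln$type == "codon") {
    chars <- c(.SENSE$codon)
    seqs <- apply(aln$states, 1, function(row)
      paste(ifelse(is.na(row), "---", chars[row]), collapse = ""))
  } else {
    seqs <- apply(aln$states, 1, function(row)
      paste(ifelse(is.na(row), "-", .NT_LEVELS[row]), collapse = ""))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", aln$taxa[i]), seqs[i]), con)
  invisible(path)
}

# Pattern compression: collapse identical site columns, returning the
# pattern matrix, weights, and for site-class models the mapping from
# original columns to patterns.
compress_patterns <- function(states, site_subset = NULL) {
  if (!is.null(site_subset)) states <- states[, site_subset, drop = FALSE]
  key <- apply(states, 2, function(col) paste(ifelse(is.na(col), 0L, col),
                                              collapse = ","))
  u <- !duplicated(key)
  idx <- match(key, key[u])
  w <- tabulate(idx, sum(u))
  list(states = states[, u, drop = FALSE], weights = w, map = idx)
}
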