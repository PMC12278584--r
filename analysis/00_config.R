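# Shared configuration for the analysis scripts. Desk-scale synthetic
# dataset: 10 taxa, 20 protein-coding loci of 40-80 codons with variable
# occupancy, a species tree with half of its internal branches forced into
# the anomaly-zone candidate range, and weak per-locus signal so the two
# gene-tree model families genuinely disagree (as single loci do).

library(gtdiscord)

MASTER_SEED <- 20260929L

CFG <- sim_config(
  n_taxa = 10L, n_loci = 20L, n_codons_range = c(40L, 80L),
  birth_rate = 1, coal_scale = 1,
  short_branch_fraction = 0.5,
  subst_scale = 0.08,
  occupancy_range = c(6L, 10L),
  seed = MASTER_SEED)

N_TARGET <- 4L      # balanced experiment size (half Est.GT.1, half Est.GT.2)
MAXIT <- 60L
RESULTS <- "results"
stage_file <- function(name) file.path(RESULTS, paste0(name, ".rds"))
dir.create(RESULTS, showWarnings = FALSE)
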