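---
title: "Models and methods behind gtdiscord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gtdiscord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtdiscord)
```

# The question the package operationalizes

Gene trees (GTs) estimated from single protein-coding loci disagree with
the species tree (ST) they evolved inside, through incomplete lineage
sorting (ILS) and through estimation and systematic error. If much of the
observed GT/ST discordance is error, then evolutionary models that describe
protein-coding sequences more faithfully — mutation–selection codon models —
should, on the same data, assign their best log-likelihood to the candidate
GT topology that is *less* discordant with the ST. gtdiscord implements
that experiment end to end on synthetic data: it simulates multispecies
coalescent (MSC) gene trees and codon alignments, infers two candidate
topologies per locus under two model families, refits all candidates under
three models, scores binary preferences, runs the statistical battery,
builds quartet-score coalescent species trees from alternative GT sets, and
scans species trees for anomaly-zone and otherwise "difficult" nodes.

# Substitution models

All rate matrices are reversible and rescaled so the expected rate at
stationarity is 1; branch lengths are expected substitutions per site
(nucleotide models) or per codon (codon models).

**GTR+G.** The general time-reversible nucleotide model with
exchangeabilities $r_{xy}$ (GT fixed at 1) and frequencies $\pi$, and an
equal-weight discrete-gamma rate mixture. Both discretizations are
available: *median* (bin medians of equal-probability bins, rescaled to
mean 1) is the default for nucleotide fits; *mean* (exact conditional bin
means, averaging to 1 by construction) is the default for codon fits.
These two defaults mirror the two conventions commonly used by nucleotide
and codon software respectively, and either can be selected everywhere.

**FMutSel0.** A mutation–selection codon model over the 61 sense codons of
the standard code. Codons $i \ne j$ differing at one nucleotide exchange at

$$q_{ij} = \mu_{ij}\, h(S_{ij}) \,\omega^{[\mathrm{nonsyn}]},\qquad
  h(S) = \frac{S}{1 - e^{-S}},\; h(0) = 1,$$

with $\mu_{ij}$ the GTR mutation rate of the changed nucleotide,
$S_{ij} = F_{aa(j)} - F_{aa(i)}$ the difference of amino-acid scaled
fitnesses, and $\omega$ multiplying nonsynonymous rates. Because
$h(S)/h(-S) = e^{S}$, the stationary distribution is available in closed
form, $\pi_j \propto \pi^{\mathrm{mut}}_j e^{F_{aa(j)}}$ with
$\pi^{\mathrm{mut}}$ the position-product (F1x4) codon frequencies; the
package asserts this analytically (left null vector) rather than solving
for it numerically. Both $F$ and $\omega$ are carried: descriptions of
FMutSel0 emphasize $\omega$ while its original definition estimates
amino-acid fitnesses, so carrying both (each fixable) covers both readings
and keeps the neutral reductions testable: $F \equiv c,\ \omega = 1$
collapses the matrix to the mutation layer exactly.

**SelAC-style stabilizing selection.** Site fitnesses decline with the
weighted physico-chemical (Grantham) distance to a site-specific optimal
amino acid $a^*_s$: the log-fitness of codon $j$ is
$-\psi\, G(aa(j), a^*_s)$ where
$G(a,b) = \sqrt{\alpha_c \Delta c^2 + \alpha_p \Delta p^2 + \alpha_v \Delta v^2}$
over Grantham's composition/polarity/volume values, and $\psi \ge 0$ is a
gene-level selection scale standing in for expression level. $\psi = 0$
collapses the model to the mutation layer (tested exactly). The per-site
optimum defaults to the *majority* amino acid observed at the site; an
ML-over-20 assignment (scoring each candidate optimum by the column's
stationary likelihood) is available behind the `optimal_aa = "ml"` flag.
The majority default was chosen because it is cheap, deterministic, and
the obvious proxy where the full multi-gene machinery of the original
SelAC estimation procedure is out of scope; the package deliberately does
not reproduce that package's shared-across-genes parameterization.

The likelihood engine is Felsenstein pruning over 4 or 61 states (C++ with
per-category scaling and analytic branch-length gradients), with gaps and
ambiguities treated as fully missing and trees treated as unrooted
(reversibility). The GTR path is cross-checked in the tests against
phangorn's independent `pml` engine to ~1e-12; the codon path against
closed forms (Jukes–Cantor reduction, zero-branch limits).

# Synthetic data: what it emulates and what it does not

`sim_config()` defaults mirror the structure of the empirical system the
analysis is designed around: 56 taxa, 40 loci of 100–500 codons, per-locus
occupancy 34–50 (always retaining a designated outgroup), and a Yule
species tree in coalescent units with a chosen fraction of internal
branches forced below 0.1 coalescent units to create anomaly-zone
candidates. Gene trees are drawn from the MSC — within a species-tree
branch of length $x$, $k$ lineages coalesce at rate $k(k-1)/2$, survivors
pass rootward, coalescence continues above the root — and the simulator's
concordance is validated against the closed form
$P(\text{concordant}) = 1 - \tfrac{2}{3}e^{-x}$. A single global
multiplier (`subst_scale`) converts coalescent lengths to substitutions
per codon: the simplest mechanism that yields realistic branch-length
heterogeneity without a per-branch population-size model.

The generator deliberately omits indels and alignment error, gene flow,
introgression and heterotachy. Passing tests therefore demonstrate
correctness of the machinery under pure-ILS discordance, not robustness of
the paper-scale conclusions to those real-data complications.

# Distances, ranking, and the retention filter

RF and path distances are computed with phangorn's `treedist` machinery
(the standard implementation of both), on unrooted topologies, branch
lengths ignored. The path distance is the Steel–Penny Euclidean form
$\sqrt{\sum_{i<j} (d_1(i,j) - d_2(i,j))^2}$ over tip-to-tip edge counts;
an absolute-sum variant sits behind a flag, because verbal descriptions of
the metric sometimes read as a plain sum while the implementation actually
run in practice is Euclidean. Normalized RF uses the standard
$\mathrm{RF} / (2(n-3))$ denominator. A locus is retained for the
experiment only when RF and path distances agree on which candidate GT is
more discordant, with ties disqualifying (the experiment needs an
unambiguous ranking); retained loci are then balanced so half have each
family's tree as the least-discordant candidate.

# The statistical battery

The headline test is a one-sample z-test on the binary outcomes with the
*sample* standard deviation ($n-1$ denominator), two-sided — the
mean-comparison convention of BSDA-style z-tests. This choice is load
bearing: with 22 successes of 38 it gives p = 0.33 and with 25 of 38 it
gives p = 0.04, the two worked values the acceptance suite pins. Secondary
tests: the exact two-sided sign (binomial) test, a 10,000-draw sign-flip
randomization test, and a two-sample Kolmogorov–Smirnov test of the
observed per-locus $\Delta$lnL values against a randomized null of 4,000
differences of pairs drawn independently with replacement from the pooled
lnLs. The pairing rule for those null differences is not uniquely
determined by its verbal description; independent with-replacement draws
for minuend and subtrahend were chosen as the least-structured option.
lnL ties (within 1e-6) are scored 0 — against the hypothesis — and logged.
No multiple-testing correction is applied across the battery; the type-I
threshold is predefined at 0.05.

## Calibration harness

`preference_calibration()` replays the entire experiment on synthetic
replicates (10 taxa, a target of 20 retained loci, reduced optimization
settings). Designing a genuine null turned out to be the subtle part, and
three ingredients matter:

1. *Exchangeable candidates.* The two candidate GTs are independent
   k-step random NNI walks from the true gene tree — identically
   constructed, hence equally wrong in distribution. (A single random NNI
   each is not equally wrong: the perturbation crossing a shorter true
   edge is easier to confuse for the truth, and 1-NNI-apart candidates
   are so similar that topology distances to any reference nearly always
   tie, starving the filter.)
2. *An uninformative ranking.* Each locus' discordance is ranked against
   its own independent random reference topology. Ranking against the
   generating species tree is not a null at all: under the MSC, whenever
   the species tree locally prefers one candidate, the true gene tree's
   deep-coalescence geometry tends to favor the same one, so outcome
   frequencies sit genuinely above 1/2 (observed 20–35% rejection) — a
   property of coalescent data, not a defect of the test. A type-I-error
   check must sever the ranking from the data; and the reference must be
   redrawn per locus, because a single reference shared across a
   replicate's loci leaves their outcomes correlated and still inflates
   the test.
3. *A working sample size.* As in the real workflow, the agreement filter
   discards most candidate loci, so each replicate filters a 6x pool down
   to (at most) the 20-locus experiment, and replicates retaining fewer
   than 10 loci are not runnable experiments and are excluded. The
   one-sample z-test's actual size at n of 10–20 ranges over roughly
   4–10% by binomial discreteness alone, which the acceptance band must
   (and does) absorb.

With this design the pooled outcome frequency is statistically
indistinguishable from 1/2. Under the power design the alignment is
simulated on whichever candidate is less discordant with the species
tree, with long even branches, so the least-discordant GT is the true
topology and the test should reject nearly always.

# Species trees, branch metrics, anomaly zone

`estimate_species_tree()` maximizes the total induced-quartet agreement
with the GT set (missing taxa contribute fewer quartets): exhaustive
enumeration up to 8 taxa, otherwise NNI hill-climbing from a greedy start
(majority consensus resolved at random when all GTs share a taxon set, NJ
on the mean topological distance matrix otherwise). The hill-climb is
monotone in the quartet score, and the suite checks NNI-mode results
against the exhaustive oracle on 6-taxon inputs.

Per-branch metrics around each internal ST edge: quartet frequencies
$q_1,q_2,q_3$ (one taxon per adjacent block, counted across GTs), support
$= q_1$ (transparent and monotone in any quartet-based posterior; externally
computed support annotations can be imported via `import_species_tree()`),
the gene concordance factor (fraction of decisive GTs containing the
branch's bipartition restricted to their taxa), and the split frequency
(fraction of all GTs containing the restricted bipartition — restriction
was chosen over requiring the full bipartition, since with variable
occupancy the full form is undefined for most GTs). Coalescent lengths
invert the MSC expectation: $x = -\ln(1.5(1 - q_1))$ for $q_1 > 1/3$, else
0, with $q_1 = 1 \mapsto \infty$.

The anomaly-zone scan applies the Degnan–Rosenberg boundary

$$a(x) = \ln\!\left[\frac{2}{3} +
  \frac{3e^{2x} - 2}{18(e^{3x} - e^{2x})}\right]$$

cascade-style to every contiguous ancestor/descendant pair of internal
branches (terminal branches excluded): the pair is anomalous iff the
descendant length $y < a(x)$. Since $a$ is strictly decreasing with root
$x^* \approx 0.2655$, no pair whose ancestor branch exceeds $x^*$ can be
anomalous. "Difficult" nodes are those meeting all four strict criteria:
coalescent length < 0.1, gCF < 10%, split frequency < 10%, support < 0.5;
an undefined metric conservatively fails its criterion, and the strict-vs-
non-strict choice at the thresholds is configurable because the convention
is not fixed by the verbal rule.

# Numerical choices

* Branch lengths are optimized on the log scale by bounded L-BFGS-B with
  analytic gradients (bounds 1e-8 to 20), convergence at an lnL change
  below ~1e-4; matrix exponentials use symmetric-similarity
  diagonalization of the reversible generator.
* Multi-start protocol: a fit is converged when two or more starts land
  within 1 lnL unit of the best; `fit_staged()` runs 4 starts and extends
  by 8 when that fails.
* The fixation factor uses the second-order expansion $1 + S/2$ for
  $|S| < 10^{-8}$ to avoid cancellation at neutrality.
* Degenerate inputs error early: stop codons (with positions), frame
  violations, empty alignment columns, leaf-set mismatches (naming the
  offending taxa), occupancy below 4, and degenerate distance-score sets
  (all pairwise distances zero).

# Problem sizes used by the tests

The suite runs at desk scale, chosen so the full battery completes in
minutes while leaving the checked quantities statistically decisive: MSC
calibration at 3,000 loci (tolerance three binomial standard errors),
experiment calibration over 300 replicate null experiments of 20 loci at
10 taxa, parameter recovery over 20 replicates of 500-codon six-taxon
alignments, and species-tree oracle checks on six-taxon fixtures. The
analysis scripts use a 10-taxon, 20-locus configuration with deliberately
weak per-locus signal (0.08 substitutions per codon per coalescent unit,
40–80 codons) — single loci must carry enough estimation error for the two
inference families to disagree, which is the regime the experiment is
about. On parameter recovery, the per-branch relative error of *any*
estimator at 500 codons is bounded below by the Fisher information at
roughly 8–11% for realistic branch lengths; the recovery check therefore
gates the branch-length *scale* (total tree length, observed error ~3%)
and $\omega$ (tolerance 20%), and reports the per-branch mean error
alongside.

# Known limitations

Tree search is NNI-only (no SPR), matching the thorough-NNI search the
workflow models; the second inference family defaults to an $\omega$-only
codon model unless a 61x61 empirical-codon-model exchangeability file is
supplied (none is bundled); the SelAC-style model fits one gene at a time
with a majority-rule optimum rather than the original shared multi-gene
machinery; quartet counting is exact only to 25 taxa (seeded subsampling
above); and the pipeline's "concatenation" reference is the true simulated
species tree, since concatenation inference itself is consumed as an input
rather than reimplemented.
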