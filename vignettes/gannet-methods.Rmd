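---
title: "Methods: GA-optimized neural network ensembles for SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-optimized neural network ensembles for SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gannet)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were settled, and what the test suite
does and does not demonstrate.

## The problem

Candidate-gene case–control studies of complex traits — here the motivating
setting is a craniofacial malformation panel of 92 SNPs genotyped in 143
cases and 119 controls — sit in an awkward regime for prediction: too few
samples for deep models on all markers, too many plausible marker subsets
for exhaustive search (choosing 10 of 92 SNPs allows
`r format(subset_search_space(92, 10), big.mark = ",")` subsets). The
package's core method couples a genetic algorithm (GA) over fixed-size SNP
subsets to small neural networks whose fit defines the GA's objective, and
averages the predictions of several independently selected subsets.

## Association scaffolding

**Quality control.** SNPs are filtered before samples: call rate ≥ 0.95,
minor allele frequency ≥ 0.01, exact Hardy–Weinberg p ≥ 0.01; then samples
with call rate < 0.95 over the retained SNPs are dropped. HWE is tested in
controls by default — deviation in cases can be a disease signal, in
controls it flags genotyping artefacts. All four thresholds are arguments
of `apply_qc()`.

**Exact tests.** `hwe_exact_test()` conditions on the minor-allele count
and sums the probabilities of all heterozygote counts no more probable than
the observed one (the standard exact HWE test). `allelic_association()`
builds the 2×2 allele table and uses the two-sided Fisher convention that
sums all tables with point probability at most the observed table's —
conventions differ across tools, so this one is stated explicitly and
pinned by enumeration oracles in the tests. The odds ratio is the sample
cross-product ratio with a Woolf log-normal 95% interval; this combination
reproduces all twelve published rows of the motivating panel's association
table from their genotype counts, which is how the "allelic, cross-product,
Woolf" interpretation was validated (a genotypic or conditional-MLE reading
does not reproduce them). One printed bound differs by one unit in the last
digit (2.10 vs 2.11) and equals the bound recomputed from the *rounded*
odds ratio — a provenance quirk of the printed table, not a method
difference.

**Risk alleles.** The risk allele of a SNP is the allele more frequent in
cases than controls (ties to the second allele), so recomputed odds ratios
are ≥ 1. When a training split is supplied, assignment uses only training
samples, keeping held-out data out of the encoding.

**LD.** Pairwise r² comes from EM haplotype-frequency estimation on
unphased genotypes (only the double heterozygote is phase-ambiguous;
convergence at 1e-8 or 1000 iterations) in the control group, the standard
background-LD practice. Pruning is greedy by ascending Fisher p: a SNP is
kept iff its r² with every kept SNP is ≤ 0.8, strictly-greater pairs being
excluded. Which member of a high-LD pair survives is not stated by the
protocol the package follows; keeping the lower-p member is consistent with
the published subset composition and is what the package does.

**Missing genotypes** are imputed deterministically from the LD structure:
the missing call takes the modal genotype among samples matching the target
sample at the SNP's highest-r² partner (partner r² ≥ 0.3), falling back to
the overall mode; ties go to the smaller genotype. The 0.3 floor avoids
conditioning on noise; the original study's imputation procedure is not
described beyond "considering the calculated LD", so this rule is the
package's documented stand-in — deterministic, auditable, and tested to
beat the unconditional mode on masked complete data.

## Polygenic risk score

PRS_j = Σ_i log(OR_i) x_ij with weights re-estimated on the training
samples only. Whether the original analysis estimated weights on all
samples is unknown; training-only is the leakage-safe default and
`compute_weights(..., sample_ids = NULL)` reproduces whole-sample weighting
if wanted. Scores are calibrated to probabilities by one-feature logistic
regression. Missing genotypes must be imputed first — there is deliberately
no per-sample renormalization by observed-call count, which would silently
change the score's scale.

## The network and its training protocol

Two dense hidden layers, each ReLU-activated, of equal width — 8, 16, 32,
64 neurons for 3-, 10-, 16-, 92-input models ("two dense layers followed by
a ReLU" is ambiguous; the two-hidden-layer reading is frozen by a
parameter-count assertion: the 3-input network has exactly
8·4 + 8·9 + 9 = 113 parameters). Other input sizes take the width of the
nearest listed size (ties toward larger). Sigmoid output, mean binary
cross-entropy, Adam with initial step 5e-3 and the classic hyperbolic decay
lr_t = lr0/(1 + 1e-5 t) per update, 100 epochs, mini-batches of 32 (the
batch size is a conventional default; the protocol's source does not state
one). After each epoch full-train and validation losses are recorded; the
restored checkpoint minimizes validation loss with ties broken toward
higher training accuracy, then the earlier epoch.

Training is implemented in C++ (RcppArmadillo) with a private mt19937
stream for initialization (Glorot uniform) and batch shuffling, so a fixed
seed gives bit-identical results run to run on a fixed build — a property
the GA's reproducibility contract inherits. Divergence (non-finite loss)
aborts with the epoch and step size in the message.

## The genetic algorithm

A chromosome is an exact k-subset of SNP ids; every operator conserves k.

* **Initialization**: individual #1 is the top-k association subset —
  seeding the search at the best marginal solution; the rest are uniform
  random k-subsets. Population 30, cycles 30 (defaults).
* **Fitness**: training loss + validation loss of the subset's network at
  the restored checkpoint (lower is better), memoized per subset so
  duplicates cost nothing. The protocol's source says only that the two
  losses are "added"; mean-per-sample cross-entropies are used. One network
  seed per GA run (not per individual) so fitness differences reflect
  subsets, not initialization noise.
* **Operators** (conventional values for fixed-size subset GAs, all
  configurable): tournament selection of size 2; subset-preserving
  crossover — child = parents' shared SNPs plus uniform draws from their
  symmetric difference up to size k; per-gene replacement mutation at 0.05
  from the unused pool; elitism 1. The source protocol does not specify
  operators.
* **Result**: the best individual ever evaluated, making best-ever fitness
  non-increasing by construction (asserted in tests).

**Ensemble**: five independent GA runs (consecutive seeds) contribute their
best subsets; the association top-k subset is always member six. "Five sets
from GA" could also mean the top five of one final population; independent
runs were chosen because they produce the subset diversity the motivating
study reports (dozens of distinct SNPs across members), and a single
population's top five are typically near-duplicates. One network per
subset; the ensemble probability is the unweighted mean of the six sigmoid
outputs, classification at ≥ 0.5 (ties to case; no threshold is stated in
the protocol). By Jensen's inequality the ensemble's Brier score never
exceeds the mean member Brier score — asserted numerically on every seeded
run in the tests.

## Data splits and evaluation

At the study size (143/119) the split is exactly 100 cases + 100 controls
for training+validation (180 train, 20 validation, stratified) and 62 test
samples (43/19). Other sizes scale the same class-balanced structure:
per-class pool m = min(floor((200/262)·n/2), n_cases − 1, n_controls − 1),
validation = 10% of the pool. Whether the original validation twenty were
class-balanced is unknown; stratified draws are used.

Metrics: accuracy at 0.5, support-weighted F1, rank-statistic AUC with ties
at half credit (equal to all-pairs enumeration; tested). The repeated-run
harness reports means and *empirical percentile* 95% intervals over 100
seeded iterations — percentile rather than normal-theory intervals because
published intervals of this kind are asymmetric about their means; the best
iteration is selected by test AUC (a flag switches to validation loss,
since the selection rule behind reported "best models" is not stated).

## The synthetic generator

`simulate_genotypes()` draws controls under HWE at specified control
risk-allele frequencies and cases under HWE at the frequency implied by the
allelic odds ratio, p_case = OR·p/(1 + p(OR − 1)) — the retrospective
sampling identity matching a case–control design. LD blocks copy a latent
anchor haplotype with an analytically derived coefficient
c = r·√(p_B q_B / (p_A q_A)) (mixture-redraw preserving each member's
marginal frequency), so target r² values are hit in expectation without a
tuning loop; infeasible targets error with the feasible maximum.
Missingness is uniform. `default_sim_spec()` mirrors the motivating panel:
92 SNPs, 143/119 samples, twelve causal SNPs at the published control RAFs
and odds ratios (1.47–2.28), two high-LD pairs at r² 0.80 and 0.98, 2%
missing calls.

Simplifications, stated plainly: case genotypes are HWE draws at the case
allele frequency (true case genotypes deviate slightly from HWE under a
multiplicative risk model); no population structure, relatedness,
genotyping-error model or recombination map; and **effects are purely
additive per SNP — the generator encodes no epistasis**.

## What the tests show — and what they cannot

The deterministic layer is tested exactly: every published association row
reproduces from its genotype counts; exact tests match full-enumeration
oracles on all small tables; the Bonferroni bound and search-space count
are exact.

The stochastic layer is tested at reduced budget (population 10, cycles 10,
epochs 50 — sizes chosen so the whole suite runs comfortably on one CPU):
with five planted causal SNPs (OR 3.0, control RAF 0.3, 500+500 samples) a
GA run recovers ≥ 3 of 5 in ≥ 80% of 20 seeded runs, best-ever fitness is
monotone in every run, and the ensemble's Brier score never exceeds its
mean member's.

One qualitative expectation does **not** hold on the additive simulation,
and the package reports this rather than hiding it: the ensemble's mean
test AUC over 20 seeds (0.684 at the study size) clearly beats every GA
member (0.588–0.626) and the mean member (0.620), but not the single
network trained on the association top-k subset (0.691, difference within
seed noise). On purely additive data the marginal-association subset is
already near-optimal, and GA subsets — selected by training+validation fit,
from a population seeded with that very subset — trade generalization for
fit. The motivating study's large real-data gain for the ensemble over the
single network plausibly rides on non-additive structure that this
generator intentionally lacks; demonstrating it would require an epistatic
simulation, which is outside the generator's defined scope.

## Numerical and degenerate-input policy

* Zero allele cells: Haldane–Anscombe 0.5 on all four cells for OR/CI
  (flagged in the result); never applied to the Fisher p.
* Monomorphic SNPs: r² = 0 with a flag; PRS weight 0 with a warning; QC
  normally removes them first.
* A SNP missing in every sample cannot be imputed and errors.
* EM for r² starts at linkage equilibrium and stops at 1e-8; r² is clamped
  to [0, 1].
* The exact binomial coefficient is computed by incremental integer-exact
  prefix products (exact below 2^53).
* All validation thresholds are strict as documented: QC uses `<` against
  minima, pruning excludes only r² strictly above 0.8, subsets use
  `p < threshold`.
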