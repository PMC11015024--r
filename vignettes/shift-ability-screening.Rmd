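---
title: "From anti-PD-1 response signatures to shift-ability screening: methods"
author: "shiftability package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From anti-PD-1 response signatures to shift-ability screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftability)
```

## The problem

Only a minority of cancer patients respond to anti-PD-1 checkpoint
blockade, and chemotherapy combinations are one practical way to widen
that minority. This package implements a desk-scale screening framework
for such combinations. It works in three stages:

1. **Signature construction.** From paired pre/on-treatment tumour
   transcriptomes with known response labels, learn two gene sets: an
   anti-PD-1 *resistance* (R) signature, whose treatment-induced
   expression increase marks non-responders, and a *sensitivity* (S)
   signature marking responders.
2. **Shift-ability screening.** Score the differential-expression
   profile of every perturbation experiment (shRNA knockdowns and
   compound treatments in cancer cell lines, Connectivity-Map level-5
   style z-score profiles) for its ability to *suppress the R program
   and induce the S program* — i.e. to shift a tumour cell from a
   resistant toward a sensitive expression state.
3. **Mechanism clustering.** Group the shifting compounds by their
   consensus expression-change signatures and annotate each cluster
   against a gene-set collection, to read off the cellular programs the
   shifting compounds engage.

## Treatment-induced expression changes

For a patient with matched samples, the treatment-induced change of a
gene is the log2 fold change between on-treatment and pre-treatment
expression; since inputs are log2-scale matrices, `treatment_induced_changes()`
is a per-patient subtraction. For cohorts without matched pairs,
`baseline_relative_changes()` centres each gene on its cohort baseline
(mean by default, median by option) as a surrogate: a sample's deviation
from the population plays the role of the treatment response. The
surrogate is weaker — it conflates patient-level baseline differences
with treatment effects — and the paired form is preferred whenever pairs
exist. Raw counts can be brought to scale with `log2(x + 1)`
(pseudocount 1 so zero counts stay at zero).

`pca_response_score()` provides the reference classifier used to
motivate the delta representation: the first principal component of the
patient-by-gene matrix, genes centred and scaled to unit variance
(zero-variance genes are dropped with a message). A principal
component's sign is arbitrary, so the score is oriented against the
labels when available (AUC at least 0.5) and otherwise by making the
loading of the lexicographically first gene non-negative — a pure
determinism convention with no statistical content.

## The enrichment engine

All three stages share one statistic: the pre-ranked GSEA enrichment
score with weighting exponent 1. Given a profile ranked descending
(ties broken by ascending gene id, so rankings are reproducible), the
running sum gains `|score|^w / sum over hits of |score|^w` at each
gene-set hit and loses `1/(N - k)` at each miss; the enrichment score
(ES) is the extreme deviation, signed. Two numerical choices matter:

* The running sum only changes slope at hits, so `prerank_es()`
  evaluates the candidate extrema (at each hit and immediately before
  each hit) rather than walking all `N` positions — an exact O(k)
  computation, verified against a brute-force running-sum oracle to
  1e-12 in the test suite and cross-checked against an independent
  implementation (`fgsea::calcGseaStat`).
* If every hit carries score exactly zero (flat profile segments, which
  do occur in integer-valued consensus signatures), the hit increments
  fall back to uniform `1/k`, keeping the score defined.

The normalized enrichment score (NES) divides the ES by the mean of
same-sign enrichment scores of random gene sets of the same effective
size, drawn without replacement from the ranked universe under a caller
seed — gene-set permutation is the only null available for pre-ranked
input. The nominal p is the fraction of same-sign null scores at least
as extreme, with a +1 pseudocount in numerator and denominator so p is
never exactly 0. Permutation draws depend only on the universe size,
the set size and the seed, so screening runs share them through a cache
with results identical to uncached computation.

A signature is scored against a profile only if it retains at least 15
genes and at least half of its members in the profile's universe;
otherwise the result is flagged as insufficient overlap rather than
silently computed on a sliver of the set. The floor is a package
convention (common GSEA practice) since no principled value exists at
this data scale.

`ssgsea_score()` implements the single-sample variant used for immune
scoring: rank-normalized expression, weighted ECDF difference between
in-set and out-of-set genes accumulated along the ranking (exponent
0.25, the usual single-sample convention), integrated and divided by
the universe size. Being rank-based, it is invariant under monotone
transformations of the expression column.

## Signature construction

`bootstrap_deg_selection()` quantifies how robustly each gene separates
responders from non-responders: 100 stratified bootstrap resamples
(each response stratum resampled with replacement to its own size,
patients — not samples — being the resampling unit), a two-sided
equal-variance Student's t test per gene per resample (Welch by
option), and a hit when p < 0.05 — an R hit when the change is higher
in non-responders, an S hit otherwise. The per-direction hit fraction
is the *DEG selection score*; a gene is at most one direction's hit per
resample, so the two fractions sum to at most 1 and are multiples of
1/100. A resample that collapses a stratum below two distinct patients
is redrawn (at most ten times); a gene with zero pooled variance in a
resample is a non-hit for it.

Candidate signatures `R_i`/`S_j` take the top `i`/`j` percent of
positive-fraction genes (count `ceiling(n * i/100)`, boundary ties all
included, so enlarging `i` never shrinks the signature).
`cross_validate_signatures()` wraps the whole procedure as a model fit:

* a stratified leave-out split (25% per class) is held back;
* the rest undergoes stratified 3-fold cross-validation; per fold, the
  bootstrap runs on the training portion only, and each grid point
  `(i, j)` is scored by the AUC of the per-patient RS score — the ES of
  `S_j` minus the ES of `R_i` in the patient's ranked changes — on the
  fold's test patients;
* core signatures at a grid point are the genes shared by all three
  fold candidates (with a flagged fallback to two-of-three when the
  full intersection is empty), and the leave-out AUC uses these cores;
* the chosen `(i, j)` maximizes the mean of cross-validation and
  leave-out AUC among grid points whose cores are size-balanced
  (smaller/larger at least 0.5), ties toward smaller signatures.

The grid default is `i, j` in 5, 10, ..., 50 percent. Patient-level RS
scoring inside the fit uses the raw ES: per-patient NES would multiply
the cost a thousandfold while the AUC, a rank statistic, is unchanged
wherever the NES transform is monotone in ES at fixed set size — the
two modes remain switchable everywhere. The entire fit is a pure
function of data, grid and seed.

**The label-permuted control.** Under permuted labels the chosen grid
point is still the argmax of a noisy objective and is therefore
optimistically biased; the honest null summary of the procedure is the
*grid-average* cross-validation AUC, which the validation suite asserts
to lie in [0.35, 0.65]. It also sits visibly below 0.5 rather than on
it: with feature selection inside the folds, a gene selected for a
spuriously positive training contrast tends to show the opposite
contrast in the held-out fold of the same finite cohort (the two
disjoint subsamples co-vary negatively around the fixed cohort mean).
This mild anti-bias is a known property of cross-validated selection,
not a defect of the implementation.

## Shift-ability screening

For a perturbation profile, `compute_shift_ability()` ranks the profile
and computes the NES of both signatures; the *shift ability* is their
deviation, `NES_S - NES_R`, positive when the perturbation suppresses
the resistance program while inducing the sensitivity program.
Significance is called two ways:

* **fixed** mode: shift ability at least 3.5 (inclusive), the compound
  screen convention;
* **empirical** mode: at least 2 SD above the mean of a per-cell-line
  null — by default the shift abilities of all *other* perturbagens in
  the same cell line (leave-one-perturbagen-out), requiring at least 30
  null scores; an explicit null can be supplied instead. shRNA screens
  default to empirical mode since their significance is defined from
  the screen's own distribution.

`screen_perturbations()` applies this per experiment and aggregates per
(perturbagen, cell line): a perturbagen shifts in a cell line when at
least one of its experiments there is significant. shRNA bookkeeping
columns record knockdown success (`knockdown_success()`, target change
at or below -1 on the z-score scale, inclusive — the scale's natural
"one SD down" unit, since no published cut exists), R-program
suppression (`NES_R < 0`) and S-program induction (`NES_S > 0`).
`integrate_screens()` finally intersects the genetic and pharmacological
evidence: a gene is a consistent synergy target when some cell line
shows both a significant shifting shRNA against it and a significant
shifting compound annotated to it, with the supporting experiment
triples returned as evidence. Compound-to-target annotation is an
explicit input mapping.

## Mechanism clustering

Per compound, each experiment's differential values are mapped to
ternary indicators (+1 above 1, -1 below -1, 0 otherwise — strict
inequalities, so exactly +/-1 maps to 0) and summed across experiments
into a consensus vector. Compounds are clustered by Ward linkage on one
minus the Pearson correlation between consensus vectors. That pairing
is mathematically loose — Ward linkage is defined for Euclidean
geometry — so the default runs the Lance-Williams `ward.D` update
directly on the correlation distance (documented as an approximation)
and a `euclidean` option runs exact Ward (`ward.D2`) on the raw
vectors. The dendrogram is cut at height 12 by default; cut heights are
linkage-scale-dependent, so when the cut yields a single cluster the
assignment falls back to k = 2 with a message — on desk-scale synthetic
data this fallback is the expected path, and it is the contract the
validation suite exercises. Each cluster's signature is the gene-wise
median consensus (arithmetic midpoint for even member counts), ranked
descending, and annotated by the enrichment engine against a user
gene-set collection with 1000 permutations.

**Multiplicity for annotation.** `annotate_cluster()` reports two
corrected columns. `fdr_q` is the pre-ranked GSEA false-discovery
q-value computed from the permutation NES null pooled across all tested
sets; `p_adjust_bh` is Benjamini-Hochberg on the per-set nominal p.
The pooled q is the primary column because the permutation nominal p is
floor-limited at roughly `1/(1 + n_same-sign_permutations)` — about
2/n_perm — so BH across a collection of m sets can never fall below
m-fold that floor at any true signal strength (about 0.1 for 51 sets at
1000 permutations), whereas the pooled null retains resolution far
below `1/n_perm`. The q column is monotonized within each sign class so
a weaker NES never receives a smaller q.

## The synthetic-data generators

The generators produce every input with known ground truth, at sizes
where the full pipeline runs in seconds:

* `simulate_cohort()` — pre-treatment expression N(8, 1) on the log2
  scale, change noise N(0, 1), 5000 genes, 200 planted genes per
  direction, 20 responders and 20 non-responders, effect size 1.5
  within-group SD of the change. The planted effect enters the *change*
  (R genes rise in non-responders, S genes in responders), which is the
  structure the signature builder assumes.
* `simulate_perturbations()` — level-5-like N(0, 1) z-score profiles,
  100 null and 10 planted experiments over 5000 genes; planted
  experiments add +2 on 100 S-like genes and -2 on 100 R-like genes.
  Metadata alternates shRNA/compound types over two round-robin cell
  lines (so each line holds enough experiments for the empirical null),
  with TAS uniform on [0.4, 1] and an optional fraction below 0.4 to
  exercise the filter.
* `simulate_mechanism_matrix()` — two disjoint 150-gene templates with
  values +/-2, ten compounds per template, three experiments per
  compound, N(0, 0.5) noise over 1000 genes.

Gaussian noise everywhere is the natural desk-scale stand-in for
z-scores and log-ratios. The generators deliberately omit gene-gene
correlation, dose-response structure and cell-line identity effects;
recovery results on them demonstrate the machinery's correctness and
calibration, not performance on real cohorts, whose effect sizes,
confounding and correlation structure are far less favourable. Sizes
(5000 genes, about 110 experiments) are the package's chosen validation
scale; the algorithms are linear in both dimensions, and scaling to
full perturbation atlases is an I/O rather than algorithmic concern.

## Degenerate inputs and edge rules

* Duplicate gene or sample identifiers anywhere are errors; gene
  symbols are opaque case-sensitive strings, never aliased.
* Genes with missing values are dropped at read time with a logged
  count; no imputation, since every downstream statistic assumes
  complete vectors.
* A gene set equal to the whole universe, or disjoint from it, cannot
  be scored (miss increment undefined / empty intersection) and errors.
* Zero-variance consensus vectors are excluded from clustering with a
  warning; a single surviving compound forms a singleton cluster.
* All scores involving permutations are bit-reproducible under a seed.

## Known limitations

* The leave-out AUC participates in grid-point selection, so the
  reported leave-out AUC at the chosen point carries mild selection
  optimism; an untouched external cohort is the only unbiased check.
* Correlation-distance Ward clustering is an approximation (above);
  clusters near the cut height can differ between the two distance
  options.
* The empirical significance null is contaminated by true shifters in
  proportion to their prevalence; with few shifters the leave-one-
  perturbagen-out rule keeps the threshold usable, but screens where
  most perturbagens shift would need an explicit null.
* The ssGSEA normalization is per-column; scores are comparable across
  samples only within a fixed gene universe.
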