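---
title: "Designing synthetic regulatory-network benchmarks for biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic regulatory-network benchmarks for biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnbench)
```

Feature-selection methods applied to case/control expression studies often
return candidate biomarker lists that barely overlap between studies. Two of
the culprits — small sample sizes relative to the feature count, and the
heterogeneity of complex disease — can be studied cleanly only on data where
the true biomarkers are known. `grnbench` builds such data by simulating a
population of gene regulatory networks, introducing a heterogeneous
"disease" through in-silico perturbations of hub genes, and then scoring
feature-ranking methods against the constructed ground truth. This vignette
documents the model, the defaults and the design decisions a maintainer
would need to know; the README shows the corresponding worked example.

## The regulatory-network model

Each subject is a network of `p` genes. The genotype is the signed sparse
connectivity matrix `W` (with `w_ij != 0` iff gene-product `j` directly
regulates gene `i`) together with per-gene kinetic parameters: the maximal
transcription rate `alpha_i` and degradation rate `beta_i`, drawn from a
hierarchical Gaussian prior (`mu_alpha = 20`, `mu_beta = 0.2`; subject-level
spreads themselves drawn from Gaussians with means 0.5 and 0.02 and
standard deviations 0.075 and 0.0025, truncated positive).

The expression dynamics are modelled as

$$\frac{dx_i}{dt} = \beta_i\,\big(\sigma(\textstyle\sum_j w_{ij} x_j + b_i) - x_i\big),$$

with logistic \(\sigma\) and basal input \(b_i = 0\) by default. We work on
the normalised expression scale \(x_i \in [0,1]\): \(\alpha_i\) only sets
the absolute transcript scale \(\alpha_i/\beta_i \cdot x_i\) and does not
move the fixed point, which is the only quantity downstream analyses use.
This choice makes the model's expression-scale thresholds (hub eligibility
at 0.88, the survival threshold near 0.81 at full scale) coherent on a
single [0, 1] scale. Transcription delays are represented implicitly by the
per-gene time constant \(1/\beta_i\); explicit delay terms are omitted
because only steady states are consumed. The phenotype of a subject is the
steady state of its network, computed by damped fixed-point iteration
(damping 0.5, falling back to 0.1 if strong feedback makes the map
oscillate; tolerance `1e-8` on the maximum update). A zero-weight network
with zero bias settles at \(x = 0.5\) everywhere, which several tests use
as an anchor.

Topologies are drawn with an exact edge count: out-degree propensities with
a Pareto tail (`hub_exponent`, default 2.3) allocate the `nnz_sub` edge
sources of the evolvable block, so a few genes become regulatory hubs;
targets are placed uniformly without self-loops. The evolvable block (the
first `n_sub` genes) is kept disconnected from the background block in both
directions, so evolution and disease can never leak into background genes —
a property the test suite asserts exactly.

## Population heterogeneity by evolution

Generation 1 consists of `M` subjects with identical connectivity. Each
subsequent generation applies three steps to the evolvable block only:

* **pairing** — each offspring takes every evolvable row (a gene's inputs)
  whole from one of two uniformly drawn parents with probability 1/2;
* **mutation** — each of the block's `nnz` nonzero weights is replaced with
  probability `0.025/nnz` by a fresh Normal(0, 1) draw, so a subject
  carries at least one mutation with probability about 0.025; the sparsity
  pattern never changes;
* **selection** — a subject survives iff the Euclidean distance of its
  steady-state phenotype from the generation-1 profile is at most `theta`.

`theta` is calibrated per run as the 99.5th percentile of phenotype
distances over probe mutants of the founder (each probe conditioned on
carrying a mutation); at the full study scale this realises a value near
0.81, which we log rather than assert because it is a realization-specific
quantity. Each generation is refilled to exactly `M` survivors by
regenerating offspring (budget `50 * M` attempts); offspring whose solver
does not converge are treated as eliminated. The per-generation counts of
mutated and eliminated subjects are logged so the progression of genotype
divergence can be inspected.

## Disease model and ground truth

The diseased phenotype perturbs **hubs**: the `k = 6` evolvable genes with
the highest out-degree among those with normalised steady expression above
`expr_min`, ties broken by higher expression then lower index. A
**knock-out** of gene `j` zeroes row `j` of `W` and clamps `x_j = 0`
persistently — without the clamp, the basal input would re-express the
gene. A **knock-down** halves row `j` and halves the gene's transcription
ceiling, capping it at half its unperturbed maximum; for an activated gene
in isolation this bounds the new steady state at half its baseline, though
joint perturbations of interacting hubs can relax the baseline-relative
bound (the ceiling bound always holds).

Each diseased subject has 4, 5 or 6 hubs affected (proportions 1/3 each,
remainders to the smaller sizes); per hub, affected subjects split 1/3
knock-out to 2/3 knock-down (remainders to knock-down). Perturbations are
applied jointly to each subject's own evolved network and the steady state
recomputed, so disease heterogeneity compounds genotype heterogeneity.

True biomarkers are the genes reachable from at least one hub in the
regulation digraph (hubs included) whose noise-free steady state moves by
more than `epsilon` under at least one single-hub knock-out or knock-down
of the founder. `epsilon` defaults to 0.01 — 1% of the dynamic range — a
value chosen to separate genuine regulatory propagation from numerical
residue; it is configurable because the model offers no canonical cutoff.

## Measurement noise and study designs

Per-gene error variances are drawn once per cohort from a lognormal whose
*variate* mean and standard deviation are 0.22 and 0.35 (the moment
identities \(\mu = \log(m^2/\sqrt{m^2+s^2})\),
\(\sigma^2 = \log(1+s^2/m^2)\) give the log-scale parameters, about
−2.1449 and 1.1233); noise is additive Gaussian with standard deviation
\(\sqrt{\mathrm{variance}}\), shared by all samples of a gene. Negative
noisy values are left unclipped by default (`clip_negative` exposes the
alternative). Cohorts of 500 + 500 (at full scale) are partitioned into
size-sets of 10 balanced, non-overlapping datasets with 50, 20, 15 or 10
subjects per group.

## The evaluation stack

Four weighting engines produce per-feature scores: absolute linear-SVM
hyperplane weights; a Gaussian-SVM criterion (change in the margin
objective when a feature is removed from the kernel — the kernel-RFE
criterion, since the margin itself does not decompose per feature); absolute
ridge-regularised discriminant coefficients from regressing the centred
class indicator (the spectral-regression formulation, solved in the dual so
`p >> n` costs only an `n x n` solve); and I-Relief margin weights
(kernelised nearest-neighbour hit/miss probabilities, iterated to
`1e-4` with a 100-iteration cap, returned non-negative and unit-sum). The
I-Relief ranking is classified with a linear SVM (the IRSVM combination).

**ERFE** (entropy-based recursive feature elimination) discards features
iteratively: weights are normalised and binned into a 10-bin histogram; when
their entropy drops below `0.5 * log(bins)` — weights concentrated on few
features — the whole lowest bin is discarded at once, otherwise the lowest
20% go. Eliminated features fill the ranking tail in elimination order.
The bin count, threshold and fallback fraction are exposed in the API and
gated by an agreement test against plain fixed-fraction RFE on separable
data. The error curve over visited model sizes is estimated by stratified
3-fold cross-validation, and the chosen model size minimises it (ties to
the smallest size).

**Hyperparameters** are tuned by a preliminary stratified 3-fold CV without
feature ranking (SVM cost; Gaussian and I-Relief bandwidths on a
median-distance grid; ridge penalty), ties resolved toward the strongest
regularisation. For I-Relief, whose weighting has no intrinsic classifier,
the bandwidth is scored by the CV error of a linear SVM on I-Relief-weighted
features — a weighting-only criterion that avoids ranking during tuning.

**Bootstrap mode** wraps tuning + ERFE in `B` external stratified
training/test splits (test fraction 1/3); held-out samples never touch
tuning or ranking. Per-split rankings merge by mean rank (Borda; ties by
mean full-model weight); error curves are evaluated on the held-out part at
a fixed geometric size grid (ratio 0.7) so they average cleanly across
splits, and the model size is chosen on the mean curve. Classification
accuracy (MCC) is always estimated on held-out data: the mean over the B
external test splits in bootstrap mode, and in single mode a stratified
3-fold external CV in which tuning, ranking and model-size choice are all
redone inside each training fold — estimating instead at the
full-data-selected feature set would let selection bias inflate the
estimate dramatically (we observed ~0.9 versus ~0.4 honest on the same
data), which is precisely the artefact external loops exist to avoid.

**SAM** computes \(d_i = (\bar x_{i2} - \bar x_{i1})/(s_i + s_0)\) with the
fudge constant \(s_0\) chosen from the percentile grid \(\{0, 5, \dots,
100\}\) of \(\{s_i\}\) to minimise the coefficient of variation of the
\(d_i\) spread across standard-error windows. The null distribution comes
from label permutations (all distinct assignments when fewer than `n_perm`
exist); p-values are pooled tail fractions with +1 smoothing. The FDR at
each cut of the \(|d|\)-ranking is the *expected* permutation
false-positive count divided by the observed count, monotonised. We use the
expectation rather than the per-permutation median: at the top of the
ranking the per-permutation counts are so discrete that their median is
zero for roughly half of global-null datasets, which would make the
procedure anticonservative exactly where calibration matters; with the
expectation, the suite verifies that permuted-label nulls select a median
of zero genes while strong signals are fully recovered at realised false
discovery proportions within the nominal 5%.

## Ranked-list stability

For complete rankings the Canberra distance
\(d(T_1, T_2) = \sum_i |\tau_1(i) - \tau_2(i)|/(\tau_1(i) + \tau_2(i))\)
(1-based ranks) measures disagreement. Partial lists of lengths
\(l_1, l_2\) over `p` features are compared through all completions of the
unlisted features over the tail positions: the **complete** distance is the
expected full distance over independent uniform completions, computed in
closed form from per-feature expectations (an unlisted feature's rank is
uniform over its tail) and required by the test suite to match exhaustive
enumeration for every list pair with `p <= 6`. The **core** distance drops
the term contributed by features unlisted in both lists, which depends only
on discarded features and would otherwise dominate short lists.

The stability indicator of a set of lists is the mean pairwise distance
normalised by the exact expectation over independent random permutation
pairs, \(E(p) = (1/p)\sum_{a,b}|a-b|/(a+b)\) (evaluated exactly up to
`p = 20000`, beyond which the continuous-limit slope \(2\log 2 - 1\) per
feature is used). Identical lists give 0, independent random lists
concentrate near 1, and systematic reversal approaches the ~1.4 maximum.
The same normalisation constant is used for partial-list indicators — the
expected distance between random *partial* lists has no closed form here,
and using \(E(p)\) keeps indicators comparable across list lengths; this is
a documented convention, not a claim of unit calibration for partial lists.

## Reduced problem sizes

The package's default `experiment_config()` is a reduced scale chosen so a
complete benchmark runs on one CPU in minutes: `p = 2000` genes with a
300-gene evolvable subnetwork, `M = 400` subjects, 30 generations, `B = 20`
bootstrap splits, 200 SAM permutations, and size-sets of 10 datasets. Three
scale couplings deserve note.

* **Edge count.** Only the full-scale realization (1619 edges among 900
  evolvable genes) is canonical. We preserve the *mean degree* (1619/900
  per gene), not the matrix density: mean degree controls the input
  distribution at the fixed point and the reachability structure, which is
  what the disease construction depends on.
* **Hub eligibility.** At 900 genes the 0.88 expression cutoff leaves a few
  dozen eligible genes; at 300 genes the same cutoff leaves a handful or
  fewer depending on the topology draw, and six hubs cannot be selected
  reliably. The reduced-scale default is `expr_min = 0.75`, which admits
  about the same top fraction of the evolvable block as 0.88 does at full
  scale; `select_hubs()` itself keeps the full-scale default and fails
  loudly when too few genes qualify.
* **Population size.** Ten non-overlapping datasets of 20 subjects per
  group need 200 subjects per class, so the reduced default is `M = 400`.

What the generator emulates — and does not. The synthetic cohorts carry
correlated features (co-regulation), population-level genotype variability,
heterogeneous multi-hub disease and gene-specific noise, which are the
phenomena the benchmark needs. They do not model probe-level microarray
artifacts, batch effects, missing values, skewed class proportions or any
real-chip preprocessing, so results transfer to real data only at the level
of method comparisons (e.g. bootstrap versus single-run stability), not
absolute performance numbers. On the reduced scale the task is *very* hard
at 10 subjects per group: gene-wise noise standard deviations near 0.47 on
a [0, 1] expression scale leave only a handful of perturbation-driven genes
individually detectable, held-out classification hovers near chance, and
median areas under the precision-recall curve fall far below 0.5. A
consequence worth stating plainly: when the held-out error curve is flat at
chance, the error-minimising model size is itself noise, so selected-list
sizes — and every quantity that depends on them, including precision at the
chosen size and the length-sensitive core stability distances — fluctuate
strongly between runs. In this regime the benefit of bootstrap resampling
over a single cross-validation does not manifest reliably; the suite
records this honestly rather than asserting it away. At larger group sizes
(or a higher-signal configuration) the selection task leaves the noise
floor, as the univariate test's small but near-perfectly precise selections
at 20 subjects per group illustrate.

## Numerical and degenerate-input conventions

* Steady-state solves warm-start from the founder phenotype; non-finite
  states raise an error naming the offending gene.
* Exactly zero sampled weights are nudged to machine epsilon so the edge
  count stays exact.
* Weight vectors that sum to zero fall back to uniform; ERFE always
  retains at least one feature per step and at least the top feature
  overall.
* Empty selections have precision reported as 0 with an explicit flag.
* MCC returns 0 whenever a denominator factor vanishes.
* All randomised operations accept explicit seeds and restore the caller's
  RNG state; composite operations derive stage seeds from a single master
  seed, so identical configurations reproduce bit-identical results.

## Known limitations

The exact dynamic equations behind the original simulator are not public;
the logistic fixed-point form above is this package's own, isolated behind
`steady_state()` so an alternative kinetics could be swapped in. The
Gaussian-SVM removal criterion, the Borda aggregation of bootstrap
rankings, and the outer-CV accuracy estimate for single runs are likewise
package choices where the literature names the component but not the
formula. Statistical comparisons (`compare_methods()`) apply paired
Wilcoxon signed-rank tests (method vs its bootstrap variant, alpha 0.05), a
Friedman test across bootstrap variants (alpha 0.05) with post-hoc pairwise
Wilcoxon at 0.05/6, and SAM-versus-rest at 0.05/8; with only 10 paired
datasets per size-set these tests are blunt instruments and should be read
as such.
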