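---
title: "Methods: a parametric background for functional-impact driver calling"
author: "finet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a parametric background for functional-impact driver calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finet)
```

## The model

`finet` calls driver genes by asking, for each gene, whether the functional
impact its mutations accumulate is larger than the gene's multi-omics
context predicts. The method has four statistical components.

**Observed FIS.** Each mutation receives a functional impact score (FIS)
from a lookup table keyed by (chromosome, position, ref, alt) —
MutationAssessor-release-3 style. Scores that cannot be looked up are
imputed by the cohort-wide mean of looked-up scores in the mutation's
effect class; when an entire class has no looked-up score (typical for
silent and truncating mutations, which protein-level scorers do not cover),
fixed values are used — silent 0, non-coding 1, non-silent 2, null 3 —
encoding the increasing severity of these classes on protein function. The
gene's observed FIS is the plain sum over all of its mutations, pooled
across patients. Silent and non-coding mutations are retained in the sum;
they contribute their (typically small) scores. The effect-class means are
cohort-wide, not per-gene: the imputation pool is defined over all
mutations with the same effect, which keeps the imputed values independent
of the gene being tested.

**Expected FIS by regression.** Somatic mutation burden varies across the
genome with expression, replication timing, chromatin state, and related
covariates, so identical observed FISs can be unremarkable for one gene and
extreme for another. A single-hidden-layer feed-forward network (100 ReLU
units) regresses observed FIS on 12 covariates; its prediction is the
gene's *expected* FIS under the no-selection hypothesis. All genes under
study are used for training, including unmutated genes with target 0, and
all 12 covariates are used even though the three MAF-derived ones partially
reflect mutation burden — the background model is supposed to absorb
burden-driven signal, leaving only functional bias in the residual.

**Local gamma null.** Genes with similar covariates share a background
regime, so the null is estimated locally: Ward clustering (minimum-variance
criterion on Euclidean distances, the squared-distance formulation) in
normalized covariate space, cut into `ceiling(G / N)` flat clusters with
N = 3000 expected genes per cluster. Within a cluster the estimated FISs
are approximately gamma — positively skewed, positive after adjustment — so
a gamma with shape α and **rate** β is fitted by maximum likelihood to the
5%-truncated values.

**Test.** The observed FIS is referred to the cluster's fitted gamma upper
tail; observed FIS ≤ 0 gets p = 1 by convention (low impact is never
evidence of driving). Benjamini–Hochberg runs within each cluster, and the
union of q ≤ 0.05 genes across clusters is the driver set.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 100 | neighbours for covariate imputation (genes) |
| `N` | 3000 | expected genes per cluster; `ceiling(G/N)` clusters |
| `hidden_units` | 100 | width of the single ReLU hidden layer |
| `epochs` | 10 | passes of Adam over the training genes |
| `truncation` | 0.05 | fraction of smallest estimated FISs dropped per cluster |
| `alpha_fdr` | 0.05 | BH q-value threshold for driver calls |
| `bh_scope` | per_cluster | BH within clusters (or `global`, pooled) |
| `output_activation` | linear | output unit; `relu` clamps predictions at 0 |

The defaults are the method's standard operating point; all are exposed in
`pipelineConfig()` because cluster granularity (`N`) and the FDR level are
the two dials with visible effect on call counts — more clusters means
tighter local nulls and more calls, and vice versa.

## Design choices where the design was open

- **Output activation.** Applying ReLU at the output would clamp all
  predictions at 0, leaving the positive-domain adjustment with nothing to
  do except at exact zeros. A linear output unit is the standard choice for
  regression and is the default; the ReLU variant is kept behind
  `output_activation = "relu"` for fidelity experiments.
- **Response standardization and initialization.** The response is
  standardized inside `trainFISModel()` and predictions are
  back-transformed; with ten epochs this matters, since Adam would
  otherwise spend its budget moving the output bias to the response mean.
  The output layer is initialized to zero so the untrained network predicts
  the response mean exactly (and a constant response is fitted exactly from
  step 0); the hidden layer uses He initialization. Optimizer: Adam,
  learning rate 0.01, batch size 32, MSE loss, no regularization or early
  stopping. Training is deterministic given the seed.
- **BH scope.** The test is framed per cluster, so BH runs within each
  cluster by default; the pooled variant is one flag away
  (`bh_scope = "global"`) because both readings are defensible. On
  identically distributed cluster p-vectors the two coincide (tested).
- **Truncation rule.** "Drop the lowest 5%" is implemented as the order
  statistic rule — remove the `floor(0.05 n)` smallest values — rather than
  an interpolated quantile; the difference is at most one value and the
  order-statistic form is exactly reproducible.
- **Domain shift.** When a cluster's truncated estimated FISs contain
  non-positive values, all values are shifted by `-min + 0.01` so the
  minimum lands at 0.01, inside the gamma domain. The observed FIS is
  tested *unshifted* (the test statistic is the observed score itself); a
  `shiftObserved` flag applies the cluster shift for sensitivity analysis.
- **Imputation geometry.** Distances between genes use only co-present
  features; gene pairs sharing no feature are at infinite distance, since
  an empty sum would spuriously read as distance zero. Neighbour sets are
  per feature (only genes observed in that feature qualify), ties at the
  K-th slot break by gene order, and imputation is a single pass on raw
  values — distances are not recomputed from partially imputed data.
  Normalization happens after imputation.
- **Gamma MLE.** Newton iteration on the profile shape equation
  `log(α) − ψ(α) = log(mean x) − mean(log x)` from a method-of-moments
  start, tolerance 1e-8, 200-iteration cap, then `β = α / mean(x)`. The
  density's β is used as a *rate* throughout, including every downstream
  tail integral. Clusters with fewer than 20 post-truncation values warn;
  fewer than 3 make the cluster unfittable and its genes get NA p-values
  rather than fabricated calls.

## What the synthetic generator emulates — and what it does not

`generateCohort()` produces the four pipeline inputs with the statistical
structure the method assumes: cluster-structured Gaussian covariates (nine
static columns; the three MAF-derived columns emerge from the generated
MAF), a smooth link (linear, quadratic, or ReLU-mix) from covariates to
each gene's expected FIS, additive Gaussian observation noise, and
mutation-level decomposition in which each gene's observed FIS is split
into per-mutation scores by random proportions (so mutation scores sum
exactly to the gene total, and conservation is testable to 1e-9).

Two generator choices deserve justification. First, the noise level:
expected FIS has standard deviation 3 on the gene scale and the default
noise s.d. is 1.1, so the covariates explain about 87% of FIS variance —
the regime these regressions reach on real cohorts, and the regime in which
a parametric background is informative. Second, driver construction:
spiked drivers have their observed FIS set to `driverEffect` times the
99.9th percentile of the null observed-FIS distribution while their
mutation *count* distribution stays identical to null genes. Drivers
therefore carry their signal in per-mutation impact, not mutation
frequency — the functional bias a function-based caller is supposed to
detect, and the situation in which frequency covariates cannot explain the
excess.

The generator deliberately does not emulate: realistic genomic positions or
trinucleotide mutation signatures; correlation between effect class and
score magnitude; patient-level heterogeneity in mutation rate; covariate
distributions with heavy tails or discreteness; or gene-length-dependent
mutation counts. Passing the validation suite therefore shows that the
pipeline is correct and calibrated *under its own model assumptions*; it
does not show robustness to the many ways real cohorts violate them (e.g.
hypermutators, which a user should filter before running).

## Validation design and problem sizes

The test suite validates each stage against independent oracles — literal
step-up enumeration for BH, exhaustive neighbour search for imputation,
patient-by-patient scans for coverage, a straight-line ReLU forward pass
for the network, method-of-moments and score-equation identities (and an
independent library optimizer) for the gamma MLE — and then validates the
pipeline statistically on synthetic cohorts of 2,000 genes × 100 patients:
20 driver-free cohorts must average fewer than one driver call (observed:
zero), p-values on draws from the fitted null must pass Kolmogorov–Smirnov
uniformity in at least 18 of 20 replicates, and 20 spiked cohorts (5%
drivers at twice the null 99.9th percentile) must reach sensitivity ≥ 0.8
at realized FDR ≤ 0.15. Regression quality is checked on held-out splits
of smooth high-signal data (R² ≥ 0.9 across five seeds). These sizes keep
the whole suite within a coffee break while leaving each statistical check
enough replicates to be meaningful.

Raw pipeline p-values on a *generated* cohort are close to, but not
exactly, uniform: the 5% truncation biases the fitted null slightly upward,
which is conservative — the direction that protects the FDR guarantee.
Uniformity is therefore asserted on draws from the fitted null itself
(which isolates the test's correctness), while cohort-level calibration is
asserted on the driver count.

## Known limitations

- The network underfits mildly at ten epochs on small cohorts; this is
  conservative (it widens the estimated-FIS spread the null is fitted to)
  but costs power on subtle drivers.
- Genes sharing a cluster with many true drivers have their null inflated
  by the drivers' *estimated* FISs only, not observed; strong contamination
  of a small cluster can still mask real signal.
- One gamma family per cluster: multimodal estimated-FIS distributions
  within a cluster (e.g. when N is set too large) are fitted poorly; lower
  `N` rather than trusting such fits.
- Symbol matching everywhere is exact string equality; harmonize aliases
  upstream.
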