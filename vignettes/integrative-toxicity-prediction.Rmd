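---
title: "Integrative prediction of multi-organ drug-induced toxicity"
author: "toxIPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative prediction of multi-organ drug-induced toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxIPS)
```

## The model and its assumptions

`toxIPS` predicts binary histopathological findings (liver and kidney) from
normalized, log-scale gene-expression profiles. The framework has two
layers.

**Per-finding layer (PPS).** For a finding $F_i$, a gene signature is
selected by ranking every gene's two-sample t-test p-value between case and
control training samples and keeping the top fraction (default 5%,
`signature_fraction`). An ensemble of $n$ k-nearest-neighbour classifiers
is then trained, each on a *jackknife sample*: all confirmed case samples
plus a random subset of controls drawn without replacement. The pathology
prediction score of sample $s$ is the ensemble mean

$$M_{F_i}(s) = \frac{1}{n} \sum_{k=1}^{n} \mathrm{sub}M_{F_i}^{k}(s),$$

where each sub-model outputs the fraction of case samples among the $k$
nearest training points (Euclidean distance on the signature genes). The
jackknife construction addresses the severe class imbalance of
histopathology data: each sub-model sees a manageable class ratio (1:1 by
default), while the ensemble as a whole still samples most of the control
population.

**Integration layer (IPS).** Findings co-occur: an injured organ presents
several related pathologies because one perturbed pathway produces multiple
symptoms. From the binary occurrence matrix $\Phi$ (samples $\times$
findings) we compute pairwise Jaccard similarities
$S(F_i,F_j) = N_{11}/(N_{01}+N_{10}+N_{11})$ — co-absence never enters — and
row-normalize them into integration weights
$N(F_i,F_j) = S(F_i,F_j)\big/\sqrt{\sum_m S(F_i,F_m)^2}$. The integrative
prediction score is the weighted combination

$$\mathrm{IPS}_{F_i}(s) = \sum_{m=1}^{k} N(F_i,F_m)\, M_{F_m}(s).$$

Because the weights are nonnegative and the self-weight dominates after
row normalization, IPS is a monotone, linear reweighting of the PPS vector:
a finding borrows evidence from the findings it historically co-occurs
with, in proportion to that co-occurrence.

Assumptions worth stating explicitly: expression values are taken as
given (complete, already normalized; the package performs no normalization
and treats missing values as errors); occurrence labels are taken as ground
truth; co-occurrence observed in training data is assumed stable enough to
transfer to test compounds; and Euclidean distance on the signature genes
is meaningful, which relies on the inputs being on a common (log) scale.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `signature_fraction` | 0.05 | fraction of the gene universe kept per signature (top p-values) |
| `knn_k` | 5 | neighbours per sub-model; odd, so neighbour votes cannot tie 50/50 |
| `n_submodels` | 25 | jackknife sub-models per finding; enough resampling to stabilize the ensemble mean at desk scale |
| `control_subset_size` | `"balanced"` | controls per jackknife sample; `"balanced"` = one per case |
| `cv_folds` | 5 | drug-grouped cross-validation folds |
| `min_drugs_per_finding` | 5 | drug-diversity filter for `filterFindings()`, applied only when requested |
| `normalization_scheme` | `"l2"` | similarity row normalization (see below) |
| `ttest_variant` | `"welch"` | unequal-variance t-test, robust to imbalance; pooled `"student"` available |
| `random_seed` | 1 | master seed; all per-finding/per-submodel seeds derived deterministically |

The ensemble size, neighbour count and control subset size are package
choices — sensible for studies of a few hundred to a few thousand samples —
not reconstructions of any particular published configuration; all are
exposed through `studyConfig()`.

## Numerical and procedural choices

* **Signature size rounding** — `ceiling(fraction * n_genes)`.
* **p-value ties** — broken by larger $|t|$, then lexicographic gene id, so
  selection is deterministic and invariant to input gene order.
* **Degenerate genes** — zero variance in both groups with equal means give
  $p = 1$ (no signal); zero variance with different means give $p = 0$.
* **Distance ties at the k-th neighbour** — resolved toward the
  lexicographically lower sample id, making neighbour sets reproducible.
* **Jaccard 0/0** — two findings with empty union get similarity 0; the
  diagonal of $S$ is fixed at 1 even for a finding with no training cases,
  so after normalization such a finding degrades to its own PPS rather than
  to a zero score.
* **Normalization scheme** — the row denominator is
  $\sqrt{\sum_m S(F_i,F_m)^2}$ by default (`l2`), which makes every row of
  $N$ unit length and the self-weight dominant. A variant without the root
  (`sum_sq`) is provided for sensitivity analysis; the choice matters only
  as a global row scaling, and thresholds are tuned on the resulting score
  scale either way.
* **IPS scale** — IPS is not clipped to $[0,1]$; thresholds are tuned on
  the IPS scale directly.
* **Decision thresholds** — chosen to maximize
  $\sqrt{\mathrm{sens} \times \mathrm{spec}}$ over the midpoints between
  consecutive distinct scores plus one candidate below the minimum and one
  above the maximum; calls use strict `>`; gmean ties break toward the
  lowest threshold (favouring sensitivity). Thresholds are tuned on
  **training-fold** scores: tuning on test predictions would leak, and a
  protocol that tuned on test scores would report systematically more
  optimistic operating points.
* **AUC** — rank-based (Mann–Whitney), ties counted half; invariant to
  monotone score transforms.
* **Cross-validation** — drugs are shuffled and dealt round-robin into
  folds (sizes differ by at most one); signatures, pathology models, $S$
  and $N$ are all refit on each fold's training data only. Findings with
  fewer than 2 training cases, or too few controls, are skipped in that
  fold with a warning, and the integration weights are restricted (and
  re-normalized) to the trainable findings. Pooled (micro-average) metrics
  over the test folds are reported, with per-fold values alongside.
* **Identity diagnostic** — `runCrossValidation(..., similarity =
  "identity")` replaces $N$ with the identity, collapsing IPS onto PPS
  exactly; this isolates the contribution of the integration layer and
  anchors the test suite.

## What the simulator emulates — and what it does not

`simulationDesign()` / `simulateStudy()` generate drug-grouped studies from
a latent-mechanism model: each drug activates a subset of latent toxicity
mechanisms; a sample's mechanism activity is its drug's activation plus
Gaussian noise; a finding occurs when its loading-weighted activity exceeds
the empirical quantile matching its target prevalence; every occurring
finding shifts its own block of signature genes by `effect_size` noise-sd
units over an i.i.d. Gaussian background. This single construction yields
the three properties the method relies on: samples grouped by compound,
correlated finding co-occurrence (shared mechanisms), and expression signal
aligned with occurrence.

Default conditions: 20 drugs × 10 samples, 1000 genes, 6 findings (3
liver, 3 kidney) on 3 mechanisms, prevalence 0.15, effect size 1.0,
10-gene signature blocks, noise sd 1. Each finding loads 1 on a primary
mechanism and 0.25–0.5 on a secondary one, so paired findings co-occur
strongly but never identically. These sizes keep a full 5-fold
cross-validation under ten seconds while leaving the classification problem
genuinely imperfect (sensitivities well below 1).

The simulator deliberately does **not** emulate probe-level artifacts,
batch effects, dose/time structure, drug-specific off-target expression, or
label noise in histopathology grading. Consequently, passing tests
demonstrate the correctness and the qualitative behaviour of the method —
not field performance on real toxicogenomics data, where those nuisances
are the main difficulty.

## The weak-finding scenario

The central claim of the integrative layer is directional: a finding that
is hard to predict on its own, but strongly co-occurs with well-predicted
findings, gains AUC under IPS. Constructing a synthetic regime where this
is visible required care, and the failure modes are instructive:

* With a rare weak finding *nested* inside strong findings (nesting is
  forced once the Jaccard similarity must be high while both findings are
  rare), the strong findings' planted genes are differential for the weak
  finding's labels too. Given enough training cases (≥ 7), the weak
  finding's own t-test discovers those borrowed genes reliably and its PPS
  is already excellent — there is nothing left for the integration to add.
* The regime that matches the motivating use case is **extreme rarity**:
  with ~3 training cases, a t-test ranking is noise-dominated (a two-sample
  t with 3 cases has so little power that hundreds of null genes outrank
  the true signal), the weak finding's signature is mostly noise, and its
  KNN ensemble ranks poorly. The strong findings' models, with more cases
  and a 2-sd effect, remain near-perfect, and the co-occurrence weights
  transfer their evidence.

The packaged scenario therefore uses 25 drugs × 8 samples, 1000 genes, one
weak finding (prevalence 0.02 → 4 cases, imbalance 1:49, effect 0.5 sd)
nested inside two strong findings (prevalence 0.04, effect 2 sd; Jaccard
0.5), 5-gene signature blocks, 5-fold drug-grouped cross-validation, 20
simulation replicates. Under these conditions the weak finding's mean
pooled AUC rises from roughly 0.87–0.89 (PPS) to roughly 0.99 (IPS), a gain
an order of magnitude above the 0.05 margin asserted in the test suite. In
a minority of replicates the weak finding has too few cases to be trainable
in enough folds to pool an AUC; those replicates are excluded from the
average (typically 18 of 20 remain).

## Limitations

* Co-occurrence weights are purely frequentist Jaccard values from the
  training folds; rare finding pairs give noisy similarities, and the
  framework has no shrinkage for them.
* IPS can propagate errors as well as evidence: a false-positive-prone
  model inflates the IPS of everything it co-occurs with (the integration
  is linear, with no gating).
* Findings skipped in a training fold simply drop out of that fold's
  integration; no imputation of their PPS is attempted.
* The t-test signature ranking uses raw p-values with no multiplicity
  correction — appropriate for ranking, but signature p-values should not
  be interpreted inferentially.
* Expression scale is taken as given (log assumed); the package neither
  checks nor transforms it.
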