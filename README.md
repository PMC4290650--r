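# toxIPS

Integrative multi-organ drug-induced toxicity prediction from
gene-expression profiles.

## The problem

Preclinical safety assessment asks whether a compound will produce
histopathological findings — liver necrosis, kidney hyaline casts,
hepatocellular hypertrophy — in treated animals. Gene-expression profiles
carry that signal, but per-finding classifiers struggle: for any one finding
the confirmed case samples are a small minority of the data (strong class
imbalance), and rare findings leave too few cases to learn a stable
expression signature. Toxicological findings do not occur independently,
though: an injured organ presents several related pathologies at once,
because one perturbed pathway produces multiple symptoms. `toxIPS`
implements a prediction framework that exploits exactly this co-occurrence
structure, for rat liver and kidney findings scored from normalized
expression matrices.

## The model

For each pathological finding *F<sub>i</sub>*:

1. **Gene signature** — a two-sample t-test ranks every gene between
   confirmed case and control training samples; the top 5% by p-value form
   the signature.
2. **Jackknife KNN ensemble** — *n* k-nearest-neighbour sub-models are
   trained, each on a jackknife sample containing *all* case samples plus a
   random control subset (by default as many controls as cases), the
   undersampling remedy for class imbalance. The **pathology prediction
   score** of a test sample *s* is the ensemble mean

   *M<sub>F_i</sub>(s) = (1/n) Σ<sub>k</sub> sub\_M<sub>F_i</sub><sup>k</sup>(s)* ∈ [0, 1],

   where each sub-model outputs the case fraction among the k nearest
   training samples (Euclidean distance on signature genes).
3. **Co-occurrence integration** — from the binary pathology occurrence
   matrix Φ (samples × findings), the pairwise Jaccard similarity
   *S(F<sub>i</sub>, F<sub>j</sub>) = N<sub>11</sub> / (N<sub>01</sub> + N<sub>10</sub> + N<sub>11</sub>)*
   is computed and row-normalized,
   *N(F<sub>i</sub>, F<sub>j</sub>) = S(F<sub>i</sub>, F<sub>j</sub>) / √(Σ<sub>m</sub> S(F<sub>i</sub>, F<sub>m</sub>)²)*.
   The **integrative prediction score** combines all findings' PPS:

   *IPS<sub>F_i</sub>(s) = Σ<sub>m</sub> N(F<sub>i</sub>, F<sub>m</sub>) · M<sub>F_m</sub>(s)*.

   A finding that strongly co-occurs with well-predicted findings borrows
   their evidence; a finding is called present when its IPS exceeds a
   threshold chosen to maximize the geometric mean of sensitivity and
   specificity.

Evaluation uses k-fold cross-validation **in the unit of drugs**: all
samples of a compound share a fold, so no compound leaks between training
and test. Signatures, models, S and N are all refit inside each training
fold.

## Worked example

The package ships a latent-mechanism simulator that generates drug-grouped
studies with correlated finding co-occurrence and planted expression
signatures, so the whole pipeline runs without any external download:

```r
library(toxIPS)

study <- simulateStudy(simulationDesign(seed = 42))
study
#> ToxicityStudy: 200 samples, 1000 genes
#>   drugs: 20  findings: 6
#>   finding prevalence: 0.15, 0.15, 0.15, 0.15, 0.15, 0.15

round(pathologySimilarity(occurrence(study))[1:3, 1:3], 2)
#>                             liver:Necrosis liver:Hypertrophy liver:Cellular infiltration
#> liver:Necrosis                        1.00              0.28                        0.25
#> liver:Hypertrophy                     0.28              1.00                        0.15
#> liver:Cellular infiltration           0.25              0.15                        1.00

report <- runCrossValidation(study, studyConfig(cv_folds = 5, random_seed = 42))
report
#> Drug-grouped 5 fold cross-validation (jaccard similarity)
#>                        finding scorer sensitivity specificity   auc threshold
#> 1         kidney:Cast, hyaline    IPS       0.867       0.988 0.989     0.952
#> 7         kidney:Cast, hyaline    PPS       0.700       0.994 0.987     0.698
#> 2              kidney:Necrosis    IPS       0.733       0.976 0.975     1.100
#> 8              kidney:Necrosis    PPS       0.367       1.000 0.970     0.710
#> ...
```

Each row gives one finding's pooled test-set operating point for the
individual score (PPS) and the integrative score (IPS). In this run the
integration lifts mean sensitivity from 0.54 to 0.75 at essentially
unchanged specificity — the co-occurrence weights let a hesitant
per-finding model be confirmed by its correlated neighbours. Thresholds are
tuned on training folds only; PPS thresholds live in [0, 1] while IPS
thresholds live on the unclipped IPS scale.

To train on one dataset and score external samples:

```r
model <- trainIntegrativeModel(study, studyConfig())
pred  <- predictIntegrative(model, newExpressionMatrix)  # $pps, $ips
```

A thin command-line front end with `simulate`, `signatures` and `evaluate`
subcommands is installed at
`system.file("scripts", "toxips.R", package = "toxIPS")`.

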