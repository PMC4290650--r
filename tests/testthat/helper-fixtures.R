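## Shared fixture builders. Everything is generated in code; no stored data.

## Tiny deterministic expression matrix with named samples/genes.
tinyExpr <- function(nSamples = 6, nGenes = 4, seed = 11) {
  set.seed(seed)
  matrix(rnorm(nSamples * nGenes),
         nSamples, nGenes,
         dimnames = list(sprintf("s%02d", seq_len(nSamples)),
                         sprintf("g%02d", seq_len(nGenes))))
}

## Small complete study via the simulator (fast defaults).
tinyStudy <- function(seed = 7, n_drugs = 8, samples_per_drug = 5,
                      n_genes = 120, effect_size = 2, ...) {
  simulateStudy(simulationDesign(
    n_drugs = n_drugs, samples_per_drug = samples_per_drug,
    n_genes = n_genes, findings = c("liver:Necrosis", "kidney:Necrosis"),
    mechanisms = 2, signature_size = 10, prevalence_target = 0.2,
    effect_size = effect_size, seed = seed, ...))
}

## Simulation design for the weak-finding / strong-neighbour scenario:
## one rare (1:49 imbalance), weak-signal (effect 0.5) finding whose
## occurrences are nested inside those of two prevalent strong-signal
## (effect 2) findings sharing its latent mechanism, giving Jaccard 0.5.
## With ~3 training cases per fold the weak finding's own t-test ranking is
## noise-dominated and its 5-gene block carries little signal, so its PPS is
## genuinely weak while the strong findings' models stay near-perfect.
weakStrongDesign <- function(seed) {
  findings <- c("liver:Single cell necrosis",  # weak, rare
                "liver:Necrosis",              # strong
                "liver:Cellular infiltration") # strong
  loading <- matrix(1, 3, 1, dimnames = list(findings, NULL))
  simulationDesign(
    n_drugs = 25, samples_per_drug = 8, n_genes = 1000,
    findings = findings, mechanisms = 1, loading = loading,
    prevalence_target = c(0.02, 0.04, 0.04),
    effect_size = c(0.5, 2, 2),
    signature_size = 5, background_noise_sd = 1,
    mechanism_noise_sd = 0.5, seed = seed)
}

## Weak-finding IPS-vs-PPS AUC gain for one simulation seed (NA when the
## weak finding was untrainable in too many folds to pool an AUC).
weakStrongGain <- function(seed) {
  study <- simulateStudy(weakStrongDesign(seed))
  cfg <- studyConfig(cv_folds = 5, random_seed = seed)
  rep <- suppressWarnings(runCrossValidation(study, cfg))
  s <- rep$summary
  w <- "liver:Single cell necrosis"
  ips <- s$auc[s$finding == w & s$scorer == "IPS"]
  pps <- s$auc[s$finding == w & s$scorer == "PPS"]
  if (!length(ips) || !length(pps)) return(c(pps = NA_real_, ips = NA_real_))
  c(pps = pps, ips = ips)
}

## Brute-force KNN score oracle: full distance sort per query.
bruteKnnScore <- function(trainFeatures, trainLabels, query, k) {
  apply(query, 1L, function(q) {
    d <- sqrt(colSums((t(trainFeatures) - q)^2))
    ord <- order(d, rownames(trainFeatures))
    mean(trainLabels[ord[seq_len(k)]])
  })
}

## Brute-force Jaccard oracle: per-sample counting loop.
bruteJaccard <- function(x, y) {
  n11 <- 0; n01 <- 0; n10 <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) n11 <- n11 + 1
    if (x[i] == 0 && y[i] == 1) n01 <- n01 + 1
    if (x[i] == 1 && y[i] == 0) n10 <- n10 + 1
  }
  if (n11 + n01 + n10 == 0) 0 else n11 / (n01 + n10 + n11)
}

## Brute-force AUC oracle: exhaustive (positive, negative) pair enumeration.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

## Brute-force threshold oracle: scan every unique score (and sentinels) for
## the best geometric mean of sensitivity/specificity under strict ">".
bruteBestGmean <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u - 1e-9, u, u + 1e-9, min(u) - 1, max(u) + 1)
  best <- 0
  for (thr in cand) {
    sens <- mean(scores[labels == 1] > thr)
    spec <- mean(scores[labels == 0] <= thr)
    best <- max(best, sqrt(sens * spec))
  }
  best
}
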