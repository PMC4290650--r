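#' Design of a simulated toxicogenomics study
#'
#' The simulator uses a latent-mechanism model: each drug activates a subset
#' of latent toxicity mechanisms; each sample's mechanism activity is its
#' drug's activation plus Gaussian noise; a finding occurs when its
#' loading-weighted activity exceeds the empirical quantile implied by its
#' prevalence target. Findings loading on shared mechanisms therefore
#' co-occur (nonzero Jaccard), and each occurring finding shifts its own
#' disjoint block of signature genes — the same causal picture
#' (perturbed pathways producing several correlated symptoms and expression
#' changes) the prediction model is built to exploit.
#'
#' Defaults are a desk-scale analogue of a multi-organ rat study: 20 drugs
#' with 10 samples each, 1000 genes, 6 findings (3 liver, 3 kidney) on 3
#' mechanisms shared by pairs of findings.
#'
#' @param n_drugs number of distinct compounds.
#' @param samples_per_drug samples per compound.
#' @param n_genes genes in the expression matrix.
#' @param findings character vector of `"organ:term"` labels.
#' @param mechanisms number of latent toxicity mechanisms.
#' @param loading findings x mechanisms nonnegative matrix; default assigns
#'   finding `i` loading 1 on its primary mechanism `1 + (i-1) %% mechanisms`
#'   and 0.25 or 0.5 (alternating) on the next one, so mechanisms are shared
#'   by several findings and co-occurrence is strong but partial, never exact.
#' @param drug_activation drugs x mechanisms matrix (binary or real); default
#'   binary with activation probability `activation_prob`.
#' @param activation_prob probability a drug activates a mechanism (used only
#'   for the default `drug_activation`).
#' @param prevalence_target per-finding case fraction in (0, 1); recycled.
#' @param effect_size per-finding expression shift of signature genes when the
#'   finding occurs, in units of `background_noise_sd`; recycled.
#' @param signature_size planted signature genes per finding; blocks are
#'   disjoint unless `signature_overlap > 0`.
#' @param signature_overlap fraction of each block shared with the previous
#'   finding's block (mimics shared-pathway genes); default 0.
#' @param background_noise_sd standard deviation of background expression.
#' @param mechanism_noise_sd per-sample noise on mechanism activity.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return validated list of class `SimulationDesign`.
#' @export
simulationDesign <- function(n_drugs = 20L,
                             samples_per_drug = 10L,
                             n_genes = 1000L,
                             findings = c("liver:Necrosis",
                                          "liver:Hypertrophy",
                                          "liver:Cellular infiltration",
                                          "kidney:Necrosis",
                                          "kidney:Regeneration",
                                          "kidney:Cast, hyaline"),
                             mechanisms = 3L,
                             loading = NULL,
                             drug_activation = NULL,
                             activation_prob = 0.35,
                             prevalence_target = 0.15,
                             effect_size = 1,
                             signature_size = 10L,
                             signature_overlap = 0,
                             background_noise_sd = 1,
                             mechanism_noise_sd = 0.5,
                             seed = 1L) {
  kF <- length(findings)
  parseFindingLabels(findings)
  if (is.null(loading)) {
    loading <- matrix(0, kF, mechanisms,
                      dimnames = list(findings, NULL))
    loading[cbind(seq_len(kF), 1L + (seq_len(kF) - 1L) %% mechanisms)] <- 1
    if (mechanisms > 1L) {
      ## secondary weight alternates so findings sharing a primary mechanism
      ## are correlated, never identical
      loading[cbind(seq_len(kF), 1L + seq_len(kF) %% mechanisms)] <-
        ifelse(seq_len(kF) %% 2L == 0L, 0.25, 0.5)
    }
  }
  loading <- as.matrix(loading)
  if (!identical(dim(loading), c(kF, as.integer(mechanisms))) ||
      any(loading < 0))
    .fail("loading must be a nonnegative findings x mechanisms matrix")
  if (!is.null(drug_activation)) {
    drug_activation <- as.matrix(drug_activation)
    if (!identical(dim(drug_activation),
                   c(as.integer(n_drugs), as.integer(mechanisms))))
      .fail("drug_activation must be drugs x mechanisms")
  }
  prevalence_target <- rep_len(prevalence_target, kF)
  effect_size <- rep_len(effect_size, kF)
  if (any(prevalence_target <= 0 | prevalence_target >= 1))
    .fail("prevalence_target must lie in (0, 1)")
  if (any(effect_size < 0)) .fail("effect_size must be >= 0")
  stride <- round(signature_size * (1 - signature_overlap))
  lastStart <- (kF - 1L) * stride
  if (lastStart + signature_size > n_genes)
    .fail("signature blocks need %d genes but n_genes is only %d",
          lastStart + signature_size, n_genes)
  structure(list(n_drugs = as.integer(n_drugs),
                 samples_per_drug = as.integer(samples_per_drug),
                 n_genes = as.integer(n_genes),
                 findings = findings,
                 mechanisms = as.integer(mechanisms),
                 loading = loading,
                 drug_activation = drug_activation,
                 activation_prob = activation_prob,
                 prevalence_target = prevalence_target,
                 effect_size = effect_size,
                 signature_size = as.integer(signature_size),
                 signature_overlap = signature_overlap,
                 background_noise_sd = background_noise_sd,
                 mechanism_noise_sd = mechanism_noise_sd,
                 seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Simulate a drug-grouped toxicogenomics study
#'
#' Draws the study described by a [simulationDesign()]: drug mechanism
#' activations (if not given), per-sample latent activities, occurrence by
#' prevalence-calibrated thresholding of the loading-weighted activity, and
#' expression as background Gaussian noise plus an `effect_size` shift of a
#' finding's signature-gene block in every sample presenting that finding.
#' Per-finding occurrence thresholds are the empirical
#' `1 - prevalence_target` quantiles of the latent scores, so the target
#' prevalence is honoured regardless of the loading scale. Fully reproducible
#' from `design$seed`.
#'
#' Samples are tagged with the organ of the majority of findings they present
#' (liver by default), a cosmetic annotation only.
#'
#' @param design a `SimulationDesign`.
#' @return a [ToxicityStudy-class] with metadata fields `design` and
#'   `signature_blocks` (the planted gene ids per finding).
#' @export
simulateStudy <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(design$seed)
  nS <- design$n_drugs * design$samples_per_drug
  kF <- length(design$findings)

  drugNames <- sprintf("drug%02d", seq_len(design$n_drugs))
  sampleIds <- sprintf("s%04d", seq_len(nS))
  geneIds <- sprintf("g%04d", seq_len(design$n_genes))
  sampleDrug <- rep(drugNames, each = design$samples_per_drug)

  act <- design$drug_activation
  if (is.null(act)) {
    act <- matrix(rbinom(design$n_drugs * design$mechanisms, 1L,
                         design$activation_prob),
                  design$n_drugs, design$mechanisms)
  }
  rownames(act) <- drugNames

  ## per-sample latent mechanism activity = drug activation + noise
  activity <- act[sampleDrug, , drop = FALSE] +
    matrix(rnorm(nS * design$mechanisms, sd = design$mechanism_noise_sd),
           nS, design$mechanisms)

  latent <- activity %*% t(design$loading)   # samples x findings
  occ <- matrix(0, nS, kF, dimnames = list(sampleIds, design$findings))
  for (j in seq_len(kF)) {
    thr <- quantile(latent[, j], probs = 1 - design$prevalence_target[j],
                    names = FALSE, type = 7)
    occ[latent[, j] > thr, j] <- 1
  }

  expr <- matrix(rnorm(nS * design$n_genes, sd = design$background_noise_sd),
                 nS, design$n_genes, dimnames = list(sampleIds, geneIds))
  stride <- round(design$signature_size * (1 - design$signature_overlap))
  blocks <- lapply(seq_len(kF), function(j) {
    start <- (j - 1L) * stride
    geneIds[seq(start + 1L, start + design$signature_size)]
  })
  names(blocks) <- design$findings
  for (j in seq_len(kF)) {
    hit <- occ[, j] == 1
    if (any(hit)) {
      expr[hit, blocks[[j]]] <- expr[hit, blocks[[j]]] +
        design$effect_size[j] * design$background_noise_sd
    }
  }

  organTag <- parseFindingLabels(design$findings)$organ
  sampleOrgan <- apply(occ, 1L, function(row) {
    pres <- organTag[row == 1]
    if (length(pres) && sum(pres == "kidney") > sum(pres == "liver"))
      "kidney" else "liver"
  })
  ann <- data.frame(sample_id = sampleIds, drug = sampleDrug,
                    organ = sampleOrgan, stringsAsFactors = FALSE)
  study <- ToxicityStudy(expr, ann, occ)
  metadata(study)$design <- design
  metadata(study)$signature_blocks <- blocks
  study
}

#' Empirical prevalence of each finding
#'
#' Column means of the binary occurrence matrix.
#'
#' @param occ binary samples x findings matrix or a [ToxicityStudy-class].
#' @return named numeric vector of per-finding case fractions.
#' @export
empiricalPrevalence <- function(occ) {
  if (is(occ, "ToxicityStudy")) occ <- occurrence(occ)
  if (!nrow(occ)) .fail("empty occurrence matrix")
  colMeans(occ)
}
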