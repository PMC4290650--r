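#' Integrative prediction score vector
#'
#' `IPS_Fi(s) = sum_m N(Fi, Fm) * M_Fm(s)`: the similarity-weighted
#' combination of all findings' pathology prediction scores, including the
#' finding's own. With nonnegative weights the combination is monotone — a
#' rise in the PPS of a positively associated finding can only raise the IPS —
#' and linear in the PPS vector. The result is not clipped to [0, 1];
#' thresholds are tuned on the IPS scale directly.
#'
#' @param N normalized similarity matrix (k x k, finding dimnames).
#' @param pps named PPS vector, finding order identical to `N`'s rows — the
#'   function errors rather than silently reordering.
#' @return named numeric IPS vector of length k.
#' @export
computeIPS <- function(N, pps) {
  if (!is.null(names(pps)) && !is.null(rownames(N)))
    .checkNamesAligned(rownames(N), names(pps), "similarity and PPS findings")
  if (ncol(N) != length(pps))
    .fail("similarity matrix is %d x %d but PPS vector has length %d",
          nrow(N), ncol(N), length(pps))
  setNames(as.numeric(N %*% pps), rownames(N))
}

#' Threshold IPS (or PPS) scores into binary finding calls
#'
#' A finding is called present when its score is strictly greater than its
#' threshold; boundary equality is called absent.
#'
#' @param scores named numeric vector per finding.
#' @param thresholds named thresholds covering every finding of `scores`.
#' @return named integer vector of calls in {0, 1}.
#' @export
predictFindings <- function(scores, thresholds) {
  missing <- setdiff(names(scores), names(thresholds))
  if (length(missing)) .fail("missing threshold for finding '%s'", missing[1L])
  setNames(as.integer(scores > thresholds[names(scores)]), names(scores))
}

#' Train the integrative model on a study
#'
#' Fits one pathology model per retained finding on the full study (during
#' cross-validation, on the training folds — see [runCrossValidation()]),
#' learns the Jaccard similarity matrix S from the same samples' occurrence
#' matrix, and row-normalizes it into the integration weights N. Findings that
#' cannot be trained (no cases, fewer than 2 cases, or not enough controls)
#' are recorded in `skipped` with a warning and take no part in the IPS
#' combination.
#'
#' @param study a [ToxicityStudy-class].
#' @param config a [studyConfig()] list.
#' @return an [IntegrativeToxModel-class].
#' @export
trainIntegrativeModel <- function(study, config = studyConfig()) {
  expr <- exprValues(study)
  occ <- occurrence(study)
  findings <- colnames(occ)
  if (is.null(findings) || length(findings) < 1L)
    .fail("study has no findings")

  models <- list()
  skipped <- data.frame(finding = character(), reason = character())
  for (i in seq_along(findings)) {
    f <- findings[i]
    seed <- deriveSeed(config$random_seed, i)
    fit <- tryCatch(
      trainPathologyModel(expr, setNames(occ[, i], rownames(occ)),
                          config = config, finding = f, seed = seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("skipping finding '%s': %s", f, conditionMessage(fit)),
              call. = FALSE)
      skipped <- rbind(skipped,
                       data.frame(finding = f, reason = conditionMessage(fit)))
    } else {
      models[[f]] <- fit
    }
  }
  S <- pathologySimilarity(occ)
  N <- normalizeSimilarity(S, scheme = config$normalization_scheme)
  new("IntegrativeToxModel",
      findings = findings, models = models,
      similarity = S, normalized = N,
      scheme = config$normalization_scheme,
      skipped = skipped, config = unclass(config))
}

#' @describeIn predictPPS samples x findings PPS matrix from an integrative
#'   model (columns of skipped findings are `NA`).
#' @export
setMethod("predictPPS", "IntegrativeToxModel", function(object, expr, ...) {
  if (is(expr, "ToxicityStudy")) expr <- exprValues(expr)
  pps <- matrix(NA_real_, nrow(expr), length(object@findings),
                dimnames = list(rownames(expr), object@findings))
  for (f in names(object@models)) {
    pps[, f] <- predictPPS(object@models[[f]], expr)
  }
  pps
})

#' Score samples with the integrative model
#'
#' Computes each trained finding's PPS for every sample, then the IPS vector
#' IPS(s) = N %*% PPS(s). When some findings were skipped in training, the
#' integration weights are restricted (and re-normalized) to the trained
#' findings, so the remaining scores stay on the same scale.
#'
#' @param model an [IntegrativeToxModel-class].
#' @param expr samples x genes matrix or a [ToxicityStudy-class].
#' @return list with matrices `pps` and `ips` (samples x findings; skipped
#'   findings are `NA`), and `findings`, the trained finding labels.
#' @export
predictIntegrative <- function(model, expr) {
  if (is(expr, "ToxicityStudy")) expr <- exprValues(expr)
  pps <- predictPPS(model, expr)
  trained <- names(model@models)
  ips <- matrix(NA_real_, nrow(expr), length(model@findings),
                dimnames = dimnames(pps))
  if (length(trained)) {
    if (length(trained) == length(model@findings)) {
      N <- model@normalized
    } else {
      N <- normalizeSimilarity(
        model@similarity[trained, trained, drop = FALSE],
        scheme = model@scheme)
    }
    ips[, trained] <- pps[, trained, drop = FALSE] %*% t(N)
  }
  list(pps = pps, ips = ips, findings = trained)
}

#' Write per-sample predictions as a long TSV
#'
#' Columns: sample_id, finding, PPS, IPS, threshold, call.
#'
#' @param pred result of [predictIntegrative()].
#' @param thresholds named per-finding thresholds on the IPS scale.
#' @param path output path.
#' @return the long-format data.frame, invisibly.
#' @export
writePredictions <- function(pred, thresholds, path) {
  fl <- pred$findings
  rows <- do.call(rbind, lapply(fl, function(f) {
    data.frame(sample_id = rownames(pred$ips), finding = f,
               PPS = pred$pps[, f], IPS = pred$ips[, f],
               threshold = thresholds[[f]],
               call = as.integer(pred$ips[, f] > thresholds[[f]]))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' @describeIn trainIntegrativeModel compact display.
#' @param object an `IntegrativeToxModel`.
#' @export
setMethod("show", "IntegrativeToxModel", function(object) {
  cat("IntegrativeToxModel:", length(object@models), "of",
      length(object@findings), "findings trained\n")
  cat("  normalization scheme:", object@scheme, "\n")
  if (nrow(object@skipped))
    cat("  skipped:", paste(object@skipped$finding, collapse = ", "), "\n")
})
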