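#' Partition drugs into balanced cross-validation folds
#'
#' Cross-validation is performed in the unit of drugs: every sample of a
#' compound falls in the same fold, so no compound leaks between training and
#' test. Drugs are shuffled and dealt round-robin, making fold drug-counts
#' differ by at most one.
#'
#' @param drugs character vector of drug identifiers (duplicates allowed; the
#'   distinct set is partitioned).
#' @param nFolds number of folds; at most the number of distinct drugs.
#' @param seed integer seed.
#' @return named integer vector mapping each distinct drug to a fold in
#'   `1..nFolds`.
#' @export
makeDrugFolds <- function(drugs, nFolds, seed) {
  uniq <- sort(unique(drugs))
  if (nFolds > length(uniq))
    .fail("nFolds (%d) exceeds the number of distinct drugs (%d)",
          nFolds, length(uniq))
  set.seed(deriveSeed(seed, 101L))
  shuffled <- sample(uniq)
  setNames(rep_len(seq_len(nFolds), length(uniq)), shuffled)
}

#' Decision threshold maximizing the geometric mean of sensitivity and
#' specificity
#'
#' Scans candidate thresholds — the midpoints between consecutive distinct
#' sorted scores, plus one candidate below the minimum and one above the
#' maximum — and returns the one maximizing `sqrt(sensitivity * specificity)`
#' with calls defined by strict `>`. The geometric mean is the standard
#' operating-point criterion for imbalanced classes. Ties are broken toward
#' the lowest threshold, favouring sensitivity.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive); both classes must be present.
#' @return list with `threshold`, `gmean`, `sensitivity`, `specificity`.
#' @export
chooseThreshold <- function(scores, labels) {
  if (length(scores) != length(labels))
    .fail("scores and labels differ in length")
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == 0))
    .fail("labels must contain at least one positive and one negative")
  u <- sort(unique(scores))
  candidates <- c(u[1L] - 1,
                  if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
                  u[length(u)] + 1)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  best <- NULL
  for (thr in candidates) {
    call <- scores > thr
    sens <- sum(call & labels == 1) / nPos
    spec <- sum(!call & labels == 0) / nNeg
    g <- sqrt(sens * spec)
    if (is.null(best) || g > best$gmean + 1e-12) {
      best <- list(threshold = thr, gmean = g,
                   sensitivity = sens, specificity = spec)
    }
  }
  best
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks: the probability that a random
#' positive scores above a random negative, with ties given half credit.
#' Invariant under any strictly monotone transform of the scores.
#'
#' @inheritParams chooseThreshold
#' @return AUC in [0, 1].
#' @export
computeAUC <- function(scores, labels) {
  labels <- as.numeric(labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    .fail("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve coordinates
#'
#' (FPR, TPR) pairs over all distinct score thresholds, for plotting or
#' export; calls use strict `>` as everywhere in the package.
#'
#' @inheritParams chooseThreshold
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocCoordinates <- function(scores, labels) {
  labels <- as.numeric(labels)
  u <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  do.call(rbind, lapply(u, function(thr) {
    call <- scores > thr
    data.frame(threshold = thr,
               fpr = sum(call & labels == 0) / nNeg,
               tpr = sum(call & labels == 1) / nPos)
  }))
}

#' Drug-grouped k-fold cross-validation of PPS and IPS
#'
#' The full evaluation protocol: drugs are partitioned into `cv_folds` balanced
#' groups; for each fold, gene signatures, pathology models, the similarity
#' matrix S and its normalized form N are all fitted on the training folds
#' only, PPS and IPS are computed for the held-out samples, and per-finding
#' decision thresholds are tuned on the training-fold scores (tuning on test
#' scores would leak). Test scores are pooled across folds (micro-average) for
#' the reported sensitivity, specificity and rank AUC of both scorers;
#' per-fold values are also returned. Findings with no trainable model in a
#' fold are skipped there with a warning.
#'
#' @param study a [ToxicityStudy-class].
#' @param config a [studyConfig()] list; `cv_folds` and `random_seed` drive
#'   the protocol.
#' @param similarity `"jaccard"` (default) learns S from the training folds;
#'   `"identity"` replaces N with the identity matrix, a diagnostic mode in
#'   which IPS reduces to PPS exactly (useful to isolate the contribution of
#'   the co-occurrence integration).
#' @return object of class `ToxicityEvaluation`: list with `summary` (one row
#'   per finding and scorer: sensitivity, specificity, auc, mean threshold),
#'   `perFold`, `skipped`, `folds` (drug -> fold map), `scores` (long
#'   data.frame of pooled test scores), and `manifest` (per-fold fingerprints
#'   of signatures, models and similarity matrices).
#' @export
runCrossValidation <- function(study, config = studyConfig(),
                               similarity = c("jaccard", "identity")) {
  similarity <- match.arg(similarity)
  expr <- exprValues(study)
  occ <- occurrence(study)
  drugs <- sampleDrugs(study)
  findings <- colnames(occ)
  folds <- makeDrugFolds(drugs, config$cv_folds, config$random_seed)

  scoreRows <- list()
  perFold <- list()
  skipped <- list()
  manifest <- list()

  for (fold in seq_len(config$cv_folds)) {
    testDrugs <- names(folds)[folds == fold]
    testIdx <- drugs %in% testDrugs
    trainIds <- names(drugs)[!testIdx]
    testIds <- names(drugs)[testIdx]
    stopifnot(length(intersect(drugs[trainIds], drugs[testIds])) == 0)

    foldConfig <- config
    foldConfig$random_seed <- deriveSeed(config$random_seed, 1000L + fold)
    trainStudy <- study[, trainIds]
    trainStudy@occurrence <- occ[trainIds, , drop = FALSE]
    model <- withCallingHandlers(
      trainIntegrativeModel(trainStudy, foldConfig),
      warning = function(w) invokeRestart("muffleWarning"))
    if (similarity == "identity") {
      I <- diag(length(model@findings))
      dimnames(I) <- dimnames(model@similarity)
      model@similarity <- I
      model@normalized <- I
    }
    if (nrow(model@skipped)) {
      skipped[[fold]] <- cbind(fold = fold, model@skipped)
    }

    trainPred <- predictIntegrative(model, expr[trainIds, , drop = FALSE])
    testPred <- predictIntegrative(model, expr[testIds, , drop = FALSE])

    manifest[[fold]] <- list(
      fold = fold,
      test_drugs = sort(testDrugs),
      trained_findings = names(model@models),
      signature_genes = lapply(model@models,
                               function(m) m@signature@geneIds),
      similarity = model@similarity,
      normalized = model@normalized)

    for (f in model@findings) {
      if (!f %in% names(model@models)) next
      for (scorer in c("PPS", "IPS")) {
        trainScores <- if (scorer == "PPS") trainPred$pps[, f] else trainPred$ips[, f]
        testScores <- if (scorer == "PPS") testPred$pps[, f] else testPred$ips[, f]
        trainLabels <- occ[trainIds, f]
        testLabels <- occ[testIds, f]
        if (!any(trainLabels == 1) || !any(trainLabels == 0)) next
        thr <- chooseThreshold(trainScores, trainLabels)$threshold
        scoreRows[[length(scoreRows) + 1L]] <- data.frame(
          fold = fold, finding = f, scorer = scorer,
          sample_id = testIds, score = unname(testScores),
          label = unname(testLabels), threshold = thr,
          call = as.integer(testScores > thr))
        if (any(testLabels == 1) && any(testLabels == 0)) {
          perFold[[length(perFold) + 1L]] <- data.frame(
            fold = fold, finding = f, scorer = scorer, threshold = thr,
            sensitivity = mean(testScores[testLabels == 1] > thr),
            specificity = mean(testScores[testLabels == 0] <= thr),
            auc = computeAUC(testScores, testLabels))
        }
      }
    }
  }

  scores <- do.call(rbind, scoreRows)
  summary <- do.call(rbind, lapply(split(scores,
                                         list(scores$finding, scores$scorer),
                                         drop = TRUE), function(d) {
    if (!any(d$label == 1) || !any(d$label == 0)) return(NULL)
    data.frame(finding = d$finding[1L], scorer = d$scorer[1L],
               sensitivity = sum(d$call == 1 & d$label == 1) / sum(d$label == 1),
               specificity = sum(d$call == 0 & d$label == 0) / sum(d$label == 0),
               auc = computeAUC(d$score, d$label),
               threshold = mean(unique(d[, c("fold", "threshold")])$threshold),
               n_case = sum(d$label == 1), n_control = sum(d$label == 0))
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$finding, summary$scorer), , drop = FALSE]

  structure(list(summary = summary,
                 perFold = if (length(perFold)) do.call(rbind, perFold) else NULL,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 folds = folds,
                 scores = scores,
                 manifest = manifest,
                 config = unclass(config),
                 similarity = similarity),
            class = "ToxicityEvaluation")
}

#' @export
print.ToxicityEvaluation <- function(x, ...) {
  cat("Drug-grouped", x$config$cv_folds, "fold cross-validation",
      sprintf("(%s similarity)\n", x$similarity))
  print(x$summary, digits = 3)
  if (!is.null(x$skipped)) {
    cat("Skipped finding/fold combinations:", nrow(x$skipped), "\n")
  }
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param report a `ToxicityEvaluation`.
#' @param path output path for the summary table.
#' @return `path` invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  write.table(report$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
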