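#' ToxicityStudy: expression, sample annotation and pathology occurrence
#'
#' Container for one toxicogenomics study. Extends
#' \linkS4class{SummarizedExperiment}: the single assay `"expr"` holds
#' normalized log-scale expression (genes in rows, samples in columns,
#' Bioconductor convention), `colData` carries the per-sample annotation
#' (`drug`, `organ`), and the extra `occurrence` slot carries the binary
#' pathology occurrence matrix Phi (samples in rows, findings in columns,
#' finding labels of the form `"organ:term"`).
#'
#' Validity requires complete numeric expression values, unique sample and
#' gene identifiers, `drug`/`organ` columns in `colData` with organ in
#' `{liver, kidney}`, and an occurrence matrix whose rows match the samples
#' exactly with entries in `{0, 1}`.
#'
#' @slot occurrence binary matrix, samples x findings.
#' @seealso [ToxicityStudy()] for the constructor, [exprValues()],
#'   [occurrence()], [sampleDrugs()], [findingNames()] for accessors.
#' @exportClass ToxicityStudy
setClass("ToxicityStudy",
         contains = "SummarizedExperiment",
         representation(occurrence = "matrix"))

setValidity("ToxicityStudy", function(object) {
  msg <- character()
  x <- assay(object, "expr")
  if (anyNA(x)) msg <- c(msg, "expression matrix contains missing values")
  if (!is.numeric(x)) msg <- c(msg, "expression matrix is not numeric")
  sid <- colnames(object)
  gid <- rownames(object)
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample ids missing or duplicated")
  if (is.null(gid) || anyDuplicated(gid))
    msg <- c(msg, "gene ids missing or duplicated")
  cd <- colData(object)
  if (!all(c("drug", "organ") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'drug' and 'organ'")
  } else if (!all(cd$organ %in% c("liver", "kidney"))) {
    msg <- c(msg, "sample organ must be 'liver' or 'kidney'")
  }
  occ <- object@occurrence
  if (!identical(rownames(occ), sid)) {
    msg <- c(msg, "occurrence rows must match sample ids in order")
  }
  if (length(occ) && !all(occ %in% c(0, 1))) {
    msg <- c(msg, "occurrence entries must be 0 or 1")
  }
  if (ncol(occ) > 0) {
    lab <- colnames(occ)
    if (is.null(lab) || anyDuplicated(lab)) {
      msg <- c(msg, "finding labels missing or duplicated")
    } else {
      ok <- tryCatch({ parseFindingLabels(lab); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) msg <- c(msg, ok)
    }
  }
  if (length(msg)) msg else TRUE
})

#' GeneSignature: per-finding t-test gene signature
#'
#' The genes most differential between confirmed case and control samples of
#' one pathological finding, ranked by increasing two-sample t-test p-value.
#' The signature size is `ceiling(fraction * n_genes)`.
#'
#' @slot finding finding label (`"organ:term"`).
#' @slot geneIds selected gene identifiers, ordered by increasing p-value.
#' @slot pValues p-values aligned with `geneIds`, non-decreasing.
#' @slot statistics t statistics aligned with `geneIds`.
#' @slot fraction the fraction of the gene universe selected.
#' @slot nGenesTotal size of the gene universe the fraction was applied to.
#' @exportClass GeneSignature
setClass("GeneSignature",
         representation(finding = "character", geneIds = "character",
                        pValues = "numeric", statistics = "numeric",
                        fraction = "numeric", nGenesTotal = "integer"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (length(object@pValues) != n || length(object@statistics) != n)
    msg <- c(msg, "geneIds, pValues and statistics must have equal length")
  if (n > 1 && any(diff(object@pValues) < 0))
    msg <- c(msg, "pValues must be sorted non-decreasing")
  if (any(object@pValues < 0 | object@pValues > 1))
    msg <- c(msg, "pValues must lie in [0, 1]")
  if (object@fraction <= 0 || object@fraction > 1)
    msg <- c(msg, "fraction must lie in (0, 1]")
  if (n != ceiling(object@fraction * object@nGenesTotal))
    msg <- c(msg, "signature size must equal ceiling(fraction * nGenesTotal)")
  if (length(msg)) msg else TRUE
})

#' PathologyModel: jackknife KNN ensemble for one finding
#'
#' One finding's trained predictor: a gene signature plus `n` KNN sub-models,
#' each fitted on a jackknife sample that contains every confirmed case and a
#' random subset of controls. The pathology prediction score (PPS) of a test
#' sample is the mean of the sub-model outputs, each output being the fraction
#' of the sample's k nearest training neighbours (Euclidean distance on the
#' signature genes) that are cases.
#'
#' @slot finding finding label.
#' @slot signature a [GeneSignature-class].
#' @slot trainFeatures training samples x signature genes matrix.
#' @slot trainLabels named binary vector (1 = case) over training samples.
#' @slot submodels list of jackknife samples; each element a list with
#'   `case_ids`, `control_ids`, `seed_used`.
#' @slot k number of nearest neighbours per sub-model.
#' @exportClass PathologyModel
setClass("PathologyModel",
         representation(finding = "character", signature = "GeneSignature",
                        trainFeatures = "matrix", trainLabels = "numeric",
                        submodels = "list", k = "integer"))

setValidity("PathologyModel", function(object) {
  msg <- character()
  if (length(object@submodels) < 1L)
    msg <- c(msg, "a PathologyModel needs at least one sub-model")
  if (!identical(rownames(object@trainFeatures), names(object@trainLabels)))
    msg <- c(msg, "trainFeatures rows must match trainLabels names")
  if (!all(object@trainLabels %in% c(0, 1)))
    msg <- c(msg, "trainLabels must be binary")
  caseIds <- names(object@trainLabels)[object@trainLabels == 1]
  for (sm in object@submodels) {
    if (!setequal(sm$case_ids, caseIds)) {
      msg <- c(msg, "every jackknife sample must contain all confirmed cases")
      break
    }
    if (anyDuplicated(sm$control_ids) ||
        !all(sm$control_ids %in% names(object@trainLabels))) {
      msg <- c(msg, "jackknife controls must be a duplicate-free subset of training controls")
      break
    }
    if (object@k > length(sm$case_ids) + length(sm$control_ids)) {
      msg <- c(msg, "k exceeds a sub-model's training size")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' IntegrativeToxModel: all pathology models plus integration weights
#'
#' The full integrative predictor: one [PathologyModel-class] per trainable
#' finding, the Jaccard co-occurrence similarity matrix S learned from the
#' training occurrence matrix, and its row-normalized form N used as
#' integration weights in IPS(s) = N %*% PPS(s).
#'
#' @slot findings ordered finding labels (all retained findings).
#' @slot models named list of [PathologyModel-class]; untrainable findings are
#'   absent.
#' @slot similarity k x k Jaccard similarity matrix S.
#' @slot normalized k x k row-normalized similarity matrix N.
#' @slot scheme normalization scheme used, `"l2"` or `"sum_sq"`.
#' @slot skipped data.frame (finding, reason) of findings without a model.
#' @slot config the [studyConfig()] list used in training.
#' @exportClass IntegrativeToxModel
setClass("IntegrativeToxModel",
         representation(findings = "character", models = "list",
                        similarity = "matrix", normalized = "matrix",
                        scheme = "character", skipped = "data.frame",
                        config = "list"))

setValidity("IntegrativeToxModel", function(object) {
  k <- length(object@findings)
  msg <- character()
  if (!identical(dim(object@similarity), c(k, k)) ||
      !identical(dim(object@normalized), c(k, k)))
    msg <- c(msg, "similarity matrices must be k x k over the findings")
  if (!all(names(object@models) %in% object@findings))
    msg <- c(msg, "models must be named by retained findings")
  if (length(msg)) msg else TRUE
})
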