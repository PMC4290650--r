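#' Draw jackknife samples for the imbalance-handling ensemble
#'
#' Each jackknife sample contains every confirmed case plus `subsetSize`
#' controls drawn without replacement, independently per sample. Undersampling
#' the control majority this way gives every sub-model a manageable class
#' ratio while the ensemble still sees most controls.
#'
#' @param caseIds confirmed case sample ids (all of them, always included).
#' @param controlIds available control sample ids.
#' @param n number of jackknife samples.
#' @param subsetSize controls per sample; must not exceed `length(controlIds)`.
#' @param seed integer seed; draws are reproducible and independent of order
#'   via per-sample derived seeds.
#' @return list of `n` lists with elements `case_ids`, `control_ids`,
#'   `seed_used`.
#' @export
drawJackknifeSamples <- function(caseIds, controlIds, n, subsetSize, seed) {
  if (n < 1L) .fail("n must be >= 1")
  if (subsetSize > length(controlIds))
    .fail("subsetSize (%d) exceeds available controls (%d)",
          subsetSize, length(controlIds))
  lapply(seq_len(n), function(i) {
    s <- deriveSeed(seed, i)
    set.seed(s)
    ctl <- sample(controlIds, subsetSize, replace = FALSE)
    list(case_ids = caseIds, control_ids = ctl, seed_used = s)
  })
}

#' KNN sub-model score
#'
#' Fraction of the k nearest training points (Euclidean distance on the
#' signature genes) that are cases. Distance ties at the k-th neighbour are
#' broken toward the lexicographically lower sample id, so neighbour sets are
#' reproducible.
#'
#' @param trainFeatures training samples x signature genes matrix (row names
#'   are sample ids).
#' @param trainLabels binary vector (1 = case) aligned with `trainFeatures`.
#' @param query numeric vector (one sample) or matrix (samples x signature
#'   genes) of query features.
#' @param k neighbours; `k <= nrow(trainFeatures)`.
#' @return numeric score(s) in [0, 1].
#' @export
knnScore <- function(trainFeatures, trainLabels, query, k) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(trainFeatures))
    .fail("query has %d features but the model expects %d",
          ncol(query), ncol(trainFeatures))
  if (k > nrow(trainFeatures))
    .fail("k (%d) exceeds training set size (%d)", k, nrow(trainFeatures))
  d2 <- .crossDist2(query, trainFeatures)
  ids <- rownames(trainFeatures)
  idRank <- order(ids)  # tie-break: lower sample id first
  tieOrder <- integer(length(ids)); tieOrder[idRank] <- seq_along(ids)
  apply(d2, 1L, function(row) {
    nb <- order(row, tieOrder)[seq_len(k)]
    mean(trainLabels[nb])
  })
}

## squared Euclidean distances between rows of a and rows of b
.crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

#' Train one finding's pathology prediction model
#'
#' Selects the gene signature on the given training data (t-test ranking of
#' cases vs controls), draws the jackknife samples and assembles the KNN
#' ensemble. The pathology prediction score (PPS) of a test sample is the mean
#' of the sub-model outputs.
#'
#' @param expr training expression matrix, samples x genes.
#' @param occurrenceColumn named binary vector over the training samples
#'   (1 = the finding was observed).
#' @param config a [studyConfig()] list.
#' @param finding finding label stored in the model.
#' @param seed integer seed for the jackknife draws (default: derived from
#'   `config$random_seed`).
#' @return a [PathologyModel-class].
#' @export
trainPathologyModel <- function(expr, occurrenceColumn, config = studyConfig(),
                                finding = NA_character_, seed = NULL) {
  ids <- rownames(expr)
  if (is.null(names(occurrenceColumn)) ||
      !identical(sort(names(occurrenceColumn)), sort(ids)))
    .fail("occurrenceColumn must be named by the training sample ids")
  occurrenceColumn <- occurrenceColumn[ids]
  caseIds <- ids[occurrenceColumn == 1]
  controlIds <- ids[occurrenceColumn == 0]
  if (length(caseIds) == 0L)
    .fail("finding '%s' untrainable: no case samples in training data", finding)
  if (length(caseIds) < 2L)
    .fail("finding '%s' untrainable: fewer than 2 case samples", finding)
  if (length(controlIds) < 2L)
    .fail("finding '%s' untrainable: fewer than 2 control samples", finding)

  subsetSize <- if (identical(config$control_subset_size, "balanced")) {
    min(length(caseIds), length(controlIds))
  } else {
    config$control_subset_size
  }
  if (subsetSize > length(controlIds))
    .fail("finding '%s' untrainable: %d controls available, %d requested",
          finding, length(controlIds), subsetSize)
  k <- config$knn_k
  if (k > length(caseIds) + subsetSize)
    .fail("finding '%s' untrainable: knn_k (%d) exceeds sub-model size (%d)",
          finding, k, length(caseIds) + subsetSize)

  sig <- buildSignature(expr, caseIds, controlIds,
                        fraction = config$signature_fraction,
                        finding = finding, variant = config$ttest_variant)
  if (is.null(seed)) seed <- deriveSeed(config$random_seed, 1L)
  sub <- drawJackknifeSamples(caseIds, controlIds, config$n_submodels,
                              subsetSize, seed)
  feat <- expr[, sig@geneIds, drop = FALSE]
  new("PathologyModel",
      finding = finding, signature = sig,
      trainFeatures = feat,
      trainLabels = setNames(as.numeric(occurrenceColumn), ids),
      submodels = sub, k = as.integer(k))
}

#' Sub-model score of a trained pathology model
#'
#' @param model a [PathologyModel-class].
#' @param which sub-model index in `1..n`.
#' @param query samples x signature-genes matrix, or a samples x genes matrix
#'   containing the signature genes.
#' @return numeric scores in [0, 1], one per query sample.
#' @export
submodelScore <- function(model, which, query) {
  sm <- model@submodels[[which]]
  ids <- c(sm$case_ids, sm$control_ids)
  query <- .alignQuery(model, query)
  knnScore(model@trainFeatures[ids, , drop = FALSE],
           model@trainLabels[ids], query, model@k)
}

.alignQuery <- function(model, query) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L,
                                           dimnames = list("query", NULL))
  sig <- model@signature@geneIds
  if (!is.null(colnames(query)) && !identical(colnames(query), sig)) {
    missing <- setdiff(sig, colnames(query))
    if (length(missing))
      .fail("query is missing signature gene '%s'", missing[1L])
    query <- query[, sig, drop = FALSE]
  } else if (ncol(query) != length(sig)) {
    .fail("query has %d features but the signature has %d genes",
          ncol(query), length(sig))
  }
  query
}

#' Pathology prediction score of a single sample
#'
#' Arithmetic mean of the n sub-model scores: the score is in [0, 1] and
#' values closer to 1 indicate that the finding is expected to occur.
#'
#' @param model a [PathologyModel-class].
#' @param features numeric vector of the sample's signature-gene expression
#'   (or a full gene vector named by gene id).
#' @return PPS in [0, 1].
#' @export
computePPS <- function(model, features) {
  unname(predictPPS(model, matrix(features, nrow = 1L,
                                  dimnames = list("s", names(features)))))
}

#' @describeIn predictPPS PPS for every row of an expression matrix. The
#'   query-to-training distance matrix is computed once on the signature genes
#'   and shared by all sub-models.
#' @export
setMethod("predictPPS", "PathologyModel", function(object, expr, ...) {
  query <- .alignQuery(object, expr)
  d2 <- .crossDist2(query, object@trainFeatures)
  ids <- rownames(object@trainFeatures)
  idRank <- order(ids)
  tieOrder <- integer(length(ids)); tieOrder[idRank] <- seq_along(ids)
  labels <- object@trainLabels
  k <- object@k
  scores <- matrix(0, nrow(query), length(object@submodels))
  for (j in seq_along(object@submodels)) {
    sm <- object@submodels[[j]]
    member <- match(c(sm$case_ids, sm$control_ids), ids)
    dj <- d2[, member, drop = FALSE]
    tj <- tieOrder[member]
    lj <- labels[member]
    scores[, j] <- apply(dj, 1L, function(row) {
      mean(lj[order(row, tj)[seq_len(k)]])
    })
  }
  setNames(rowMeans(scores), rownames(query))
})
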