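#' Jaccard similarity between two binary occurrence vectors
#'
#' `N11 / (N01 + N10 + N11)`, where `N11` counts samples in which both
#' findings occur and `N01`/`N10` count samples in which exactly one does.
#' Co-absence (`N00`) never enters, so adding samples in which neither finding
#' occurs leaves the similarity unchanged. Two all-zero vectors have an empty
#' union; that 0/0 case is defined as 0.
#'
#' @param x,y equal-length binary vectors.
#' @return similarity in [0, 1].
#' @export
jaccardSimilarity <- function(x, y) {
  if (length(x) != length(y))
    .fail("occurrence vectors differ in length (%d vs %d)", length(x), length(y))
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    .fail("occurrence vectors must be binary")
  n11 <- sum(x == 1 & y == 1)
  union <- sum(x == 1 | y == 1)
  if (union == 0) 0 else n11 / union
}

#' Pairwise Jaccard similarity matrix over all findings
#'
#' Builds the k x k pathology similarity matrix S from a binary occurrence
#' matrix. The diagonal is 1: exactly the Jaccard of a nonzero column with
#' itself, and fixed to 1 for a finding with no cases so that such a finding
#' degrades gracefully to its own PPS after normalization rather than to a
#' zero score. During cross-validation the caller must pass training-fold
#' samples only.
#'
#' @param occ binary samples x findings matrix (k >= 1).
#' @return symmetric k x k matrix with entries in [0, 1] and unit diagonal.
#' @export
pathologySimilarity <- function(occ) {
  occ <- as.matrix(occ)
  if (ncol(occ) < 1L) .fail("need at least one finding")
  n11 <- crossprod(occ)                       # co-occurrence counts
  colsum <- colSums(occ)
  union <- outer(colsum, colsum, `+`) - n11   # |Fi| + |Fj| - |Fi & Fj|
  S <- ifelse(union > 0, n11 / union, 0)
  diag(S) <- 1
  dimnames(S) <- list(colnames(occ), colnames(occ))
  S
}

#' Row-normalize a similarity matrix into integration weights
#'
#' Under the default `"l2"` scheme, row i of N is row i of S divided by the
#' Euclidean norm of row i, so every row has unit length and the self-weight
#' dominates. The `"sum_sq"` scheme divides by the plain sum of squares (no
#' root) instead, for sensitivity analysis. N is generally not symmetric even
#' though S is.
#'
#' @param S symmetric similarity matrix with nonnegative entries; rows must
#'   not be all-zero (the unit diagonal of [pathologySimilarity()] guarantees
#'   this).
#' @param scheme `"l2"` (default) or `"sum_sq"`.
#' @return the normalized matrix N, same dimnames as S.
#' @export
normalizeSimilarity <- function(S, scheme = c("l2", "sum_sq")) {
  scheme <- match.arg(scheme)
  S <- as.matrix(S)
  ss <- rowSums(S^2)
  if (any(ss == 0))
    .fail("row '%s' of the similarity matrix is all zero",
          rownames(S)[which(ss == 0)[1L]] %||% which(ss == 0)[1L])
  denom <- if (scheme == "l2") sqrt(ss) else ss
  S / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a similarity matrix as a labelled square TSV
#'
#' @param S square matrix with finding dimnames.
#' @param path output path.
#' @return `path` invisibly.
#' @export
writeSimilarityMatrix <- function(S, path) {
  df <- data.frame(finding = rownames(S), S, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
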