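#' Per-gene two-sample t-tests between case and control samples
#'
#' Vectorized two-sided two-sample t-test across all genes of an expression
#' matrix. Welch's unequal-variance form is the default (robust to the strong
#' case/control imbalance typical of histopathology data); the pooled Student
#' form is available behind `variant`.
#'
#' Genes with zero variance in both groups and equal group means carry no
#' signal and get p = 1 by convention. A zero-variance gene whose group means
#' differ separates the groups perfectly and gets p = 0 (infinite t).
#'
#' @param expr samples x genes matrix.
#' @param caseIds,controlIds disjoint sample id sets, each of size >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @return list with numeric vectors `p` (two-sided p-values) and `statistic`
#'   (t statistics, case minus control), both in `expr`'s gene order.
#' @export
geneTTests <- function(expr, caseIds, controlIds,
                       variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(intersect(caseIds, controlIds)))
    .fail("case and control sample sets overlap")
  missing <- setdiff(c(caseIds, controlIds), rownames(expr))
  if (length(missing)) .fail("sample '%s' not in expression matrix", missing[1L])
  n1 <- length(caseIds); n2 <- length(controlIds)
  if (n1 < 2L || n2 < 2L)
    .fail("each group needs at least 2 samples (got %d cases, %d controls)", n1, n2)

  x <- expr[caseIds, , drop = FALSE]
  y <- expr[controlIds, , drop = FALSE]
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums((x - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((y - rep(m2, each = n2))^2) / (n2 - 1)
  dm <- m1 - m2

  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(se2))
  }

  tstat <- dm / sqrt(se2)
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  degenerate <- se2 == 0
  tstat[degenerate] <- ifelse(dm[degenerate] == 0, 0, Inf * sign(dm[degenerate]))
  p[degenerate] <- ifelse(dm[degenerate] == 0, 1, 0)
  list(p = setNames(p, colnames(expr)),
       statistic = setNames(tstat, colnames(expr)))
}

#' Select a gene signature from per-gene p-values
#'
#' Keeps the `ceiling(fraction * n_genes)` genes with the smallest p-values,
#' ranked in increasing order. Ties in p are broken by larger |t| statistic,
#' then by gene id, so the selection is deterministic and invariant to the
#' input's gene order.
#'
#' @param pValues named per-gene p-values.
#' @param fraction fraction of genes to keep, in (0, 1].
#' @param statistics optional named t statistics for tie-breaking.
#' @param finding finding label recorded in the signature.
#' @return a [GeneSignature-class].
#' @export
selectSignature <- function(pValues, fraction, statistics = NULL,
                            finding = NA_character_) {
  if (!length(pValues)) .fail("empty p-value vector")
  if (fraction <= 0 || fraction > 1) .fail("fraction must lie in (0, 1]")
  if (is.null(names(pValues))) .fail("pValues must be named by gene id")
  if (is.null(statistics)) statistics <- setNames(rep(0, length(pValues)),
                                                  names(pValues))
  statistics <- statistics[names(pValues)]
  nSel <- as.integer(ceiling(fraction * length(pValues)))
  ord <- order(pValues, -abs(statistics), names(pValues))
  sel <- ord[seq_len(nSel)]
  new("GeneSignature",
      finding = finding,
      geneIds = names(pValues)[sel],
      pValues = unname(pValues[sel]),
      statistics = unname(statistics[sel]),
      fraction = fraction,
      nGenesTotal = length(pValues))
}

#' Build a finding's signature from training data
#'
#' Convenience wrapper: t-tests on the given case/control split, then top-
#' fraction selection. During cross-validation this is called inside every
#' training fold, never on the full data, to avoid overfitting the signature.
#'
#' @inheritParams geneTTests
#' @inheritParams selectSignature
#' @return a [GeneSignature-class].
#' @export
buildSignature <- function(expr, caseIds, controlIds, fraction = 0.05,
                           finding = NA_character_,
                           variant = c("welch", "student")) {
  tt <- geneTTests(expr, caseIds, controlIds, variant = match.arg(variant))
  selectSignature(tt$p, fraction, statistics = tt$statistic, finding = finding)
}

#' Persist / load a gene signature as two-column TSV
#'
#' @param signature a [GeneSignature-class].
#' @param path output TSV path (columns gene_id, p_value).
#' @return `path` invisibly.
#' @export
writeSignature <- function(signature, path) {
  write.table(data.frame(gene_id = signature@geneIds,
                         p_value = signature@pValues),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
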