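#' Construct a ToxicityStudy
#'
#' Assembles the three canonical tables of a toxicogenomics study into one
#' validated object. The expression matrix uses the canonical text layout
#' (samples in rows, genes in columns); internally it is stored transposed in
#' the SummarizedExperiment convention.
#'
#' @param expr numeric matrix, samples x genes, with unique row and column
#'   names; normalized log-scale intensities, no missing values.
#' @param annotation data.frame with columns `sample_id`, `drug`, `organ`
#'   (organ in `{liver, kidney}`); one row per sample of `expr`.
#' @param occurrence binary matrix, samples x findings; row names match the
#'   samples of `expr`, column names are `"organ:term"` finding labels.
#' @return a [ToxicityStudy-class].
#' @examples
#' design <- simulationDesign(n_drugs = 4, samples_per_drug = 3, n_genes = 50)
#' study <- simulateStudy(design)
#' study
#' @export
ToxicityStudy <- function(expr, annotation, occurrence) {
  expr <- as.matrix(expr)
  if (anyDuplicated(rownames(expr)))
    .fail("duplicated sample id '%s' in expression matrix",
          rownames(expr)[duplicated(rownames(expr))][1L])
  if (anyDuplicated(colnames(expr)))
    .fail("duplicated gene id '%s' in expression matrix",
          colnames(expr)[duplicated(colnames(expr))][1L])
  req <- c("sample_id", "drug", "organ")
  if (!all(req %in% colnames(annotation)))
    .fail("annotation must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(annotation$sample_id))
    .fail("duplicated sample id '%s' in annotation",
          annotation$sample_id[duplicated(annotation$sample_id)][1L])
  missing <- setdiff(annotation$sample_id, rownames(expr))
  if (length(missing))
    .fail("annotation sample '%s' not present in expression matrix", missing[1L])
  missing <- setdiff(rownames(expr), annotation$sample_id)
  if (length(missing))
    .fail("expression sample '%s' missing from annotation", missing[1L])
  ann <- annotation[match(rownames(expr), annotation$sample_id), , drop = FALSE]

  occurrence <- as.matrix(occurrence)
  storage.mode(occurrence) <- "double"
  if (!identical(sort(rownames(occurrence)), sort(rownames(expr))))
    .fail("occurrence matrix samples do not match expression samples")
  occurrence <- occurrence[rownames(expr), , drop = FALSE]

  se <- SummarizedExperiment(
    assays = list(expr = t(expr)),
    colData = DataFrame(drug = ann$drug, organ = ann$organ,
                        row.names = ann$sample_id))
  new("ToxicityStudy", se, occurrence = occurrence)
}

#' @rdname ToxicityStudy
#' @return `exprValues` returns the expression matrix in the canonical
#'   samples x genes layout.
#' @export
setMethod("exprValues", "ToxicityStudy", function(x) t(assay(x, "expr")))

#' @rdname ToxicityStudy
#' @return `occurrence` returns the binary samples x findings matrix Phi.
#' @export
setMethod("occurrence", "ToxicityStudy", function(x) x@occurrence)

#' @rdname ToxicityStudy
#' @return `sampleDrugs`/`sampleOrgans` return named character vectors over
#'   samples.
#' @export
setMethod("sampleDrugs", "ToxicityStudy",
          function(x) setNames(as.character(colData(x)$drug), colnames(x)))

#' @rdname ToxicityStudy
#' @export
setMethod("sampleOrgans", "ToxicityStudy",
          function(x) setNames(as.character(colData(x)$organ), colnames(x)))

#' @rdname ToxicityStudy
#' @return `findingNames` returns the `"organ:term"` finding labels.
#' @export
setMethod("findingNames", "ToxicityStudy", function(x) colnames(x@occurrence))

#' @describeIn ToxicityStudy subset by gene (`i`) and/or sample (`j`); the
#'   occurrence matrix follows the sample subset.
#' @param i,j,drop gene and sample subscripts (drop is ignored).
#' @export
setMethod("[", c("ToxicityStudy", "ANY", "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  if (!missing(j)) {
    out@occurrence <- x@occurrence[j, , drop = FALSE]
  }
  out
})

#' @describeIn ToxicityStudy compact display.
#' @param object a `ToxicityStudy`.
#' @export
setMethod("show", "ToxicityStudy", function(object) {
  cat("ToxicityStudy:", ncol(object), "samples,", nrow(object), "genes\n")
  cat("  drugs:", length(unique(colData(object)$drug)),
      " findings:", ncol(object@occurrence), "\n")
  prev <- if (ncol(object@occurrence)) {
    paste0(sprintf("%.2f", colMeans(object@occurrence)), collapse = ", ")
  } else "none"
  cat("  finding prevalence:", prev, "\n")
})
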