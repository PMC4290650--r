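## Delimited-text readers and writers for the three canonical tables.
## Dialect: tab-delimited UTF-8, one header row, first column holds ids;
## comma supported via `sep`, never inferred. Missing values are an error —
## the pipeline consumes complete, already-normalized matrices.

.readTable <- function(path, sep) {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .fail("file '%s' has no data columns", path)
  df
}

.checkNumericCells <- function(df, path) {
  ids <- df[[1L]]
  for (j in seq(2L, ncol(df))) {
    col <- df[[j]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(col))
    if (length(bad)) {
      .fail("non-numeric or missing value in '%s' at row '%s', column '%s'",
            path, ids[bad[1L]], colnames(df)[j])
    }
    df[[j]] <- col
  }
  df
}

#' Read an expression matrix from delimited text
#'
#' Reads a normalized expression table with one header row and the ids in the
#' first column, and returns it in the canonical samples x genes layout.
#'
#' @param path path to a delimited text file.
#' @param orientation `"samples_in_rows"` (rows are samples) or
#'   `"genes_in_rows"` (rows are genes; the matrix is transposed on read).
#' @param sep field separator; tab by default, comma via `sep = ","`.
#' @return numeric matrix, samples x genes.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("samples_in_rows", "genes_in_rows"),
                                 sep = "\t") {
  orientation <- match.arg(orientation)
  df <- .checkNumericCells(.readTable(path, sep), path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) .fail("duplicated id '%s' in '%s'", dup[1L], path)
  dup <- colnames(df)[-1L][duplicated(colnames(df)[-1L])]
  if (length(dup)) .fail("duplicated id '%s' in '%s'", dup[1L], path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "genes_in_rows") m <- t(m)
  m
}

#' Write an expression matrix as delimited text
#'
#' @param x samples x genes numeric matrix.
#' @param path output path.
#' @param digits significant digits printed; round-trips exactly through
#'   [readExpressionMatrix()] at this precision.
#' @param sep field separator.
#' @param idColumn header name of the id column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, digits = 12, sep = "\t",
                                  idColumn = "sample_id") {
  df <- data.frame(id = rownames(x),
                   signif(x, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' @param path delimited text with columns `sample_id`, `drug`, `organ`.
#' @param sep field separator.
#' @return data.frame with the three columns; sample ids unique, organs in
#'   `{liver, kidney}`.
#' @export
readSampleAnnotation <- function(path, sep = "\t") {
  df <- .readTable(path, sep)
  req <- c("sample_id", "drug", "organ")
  if (!all(req %in% colnames(df)))
    .fail("'%s' must have columns %s", path, paste(req, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) .fail("duplicated sample id '%s' in '%s'", dup[1L], path)
  bad <- !df$organ %in% c("liver", "kidney")
  if (any(bad))
    .fail("unknown organ '%s' for sample '%s' in '%s'",
          df$organ[which(bad)[1L]], df$sample_id[which(bad)[1L]], path)
  df[, req]
}

#' @rdname readSampleAnnotation
#' @param x annotation data.frame.
#' @export
writeSampleAnnotation <- function(x, path, sep = "\t") {
  write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary pathology occurrence matrix
#'
#' The header names the findings as `"organ:term"` (e.g. `liver:Necrosis`);
#' every cell must be 0 or 1.
#'
#' @param path delimited text file, samples in rows.
#' @param sep field separator.
#' @return binary matrix, samples x findings.
#' @export
readOccurrenceMatrix <- function(path, sep = "\t") {
  df <- .checkNumericCells(.readTable(path, sep), path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) .fail("duplicated sample id '%s' in '%s'", dup[1L], path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  parseFindingLabels(colnames(m))  # errors on malformed or unknown-organ labels
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad)) {
    .fail("occurrence cell not in {0,1} in '%s' at row '%s', column '%s' (value %s)",
          path, rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
          format(m[bad[1L, , drop = FALSE]]))
  }
  m
}

#' @rdname readOccurrenceMatrix
#' @param x binary samples x findings matrix.
#' @export
writeOccurrenceMatrix <- function(x, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(x), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a full study from the three canonical files
#'
#' @param exprPath,annPath,occPath paths to the expression, annotation and
#'   occurrence tables.
#' @param orientation orientation of the expression file.
#' @param sep field separator.
#' @return a [ToxicityStudy-class].
#' @export
readStudy <- function(exprPath, annPath, occPath,
                      orientation = "samples_in_rows", sep = "\t") {
  ToxicityStudy(readExpressionMatrix(exprPath, orientation, sep),
                readSampleAnnotation(annPath, sep),
                readOccurrenceMatrix(occPath, sep))
}

#' Keep only findings induced by enough distinct drugs
#'
#' A finding is retained when its case samples span at least `minDrugs`
#' distinct compounds; rarer findings carry too little drug diversity to learn
#' from. Column order is preserved, and the filter is idempotent.
#'
#' @param occ binary samples x findings matrix, or a [ToxicityStudy-class].
#' @param annotation annotation data.frame (ignored for a `ToxicityStudy`).
#' @param minDrugs minimum number of distinct case drugs (default 5).
#' @return the input with non-qualifying finding columns dropped.
#' @export
filterFindings <- function(occ, annotation = NULL, minDrugs = 5) {
  if (is(occ, "ToxicityStudy")) {
    kept <- filterFindings(occurrence(occ),
                           data.frame(sample_id = colnames(occ),
                                      drug = sampleDrugs(occ)),
                           minDrugs)
    occ@occurrence <- kept
    validObject(occ)
    return(occ)
  }
  if (!identical(sort(rownames(occ)), sort(annotation$sample_id)))
    .fail("occurrence samples and annotation samples do not match")
  drugs <- setNames(as.character(annotation$drug), annotation$sample_id)
  drugs <- drugs[rownames(occ)]
  nCaseDrugs <- apply(occ, 2L, function(col) length(unique(drugs[col == 1])))
  occ[, nCaseDrugs >= minDrugs, drop = FALSE]
}
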