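## Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer mixing so that per-finding and per-submodel random
#' draws are reproducible regardless of evaluation order (serial or parallel).
#' All arithmetic stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... nonnegative integer indices (e.g. finding index, submodel index).
#' @return a positive integer seed.
#' @keywords internal
deriveSeed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1
  x <- as.double(master %% m)
  for (idx in c(...)) {
    x <- (x * 48271 + as.double(idx) * 65537 + 1) %% m
  }
  as.integer(x %% (m - 1L)) + 1L
}

## stopifnot with a formatted message
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.checkNamesAligned <- function(a, b, what) {
  if (length(a) != length(b) || !all(a == b)) {
    .fail("%s are not aligned (order and identity must match exactly)", what)
  }
  invisible(TRUE)
}

#' Parse "organ:term" finding labels
#'
#' Finding columns are labelled `organ:term` (e.g. `"liver:Necrosis"`) so that
#' the liver/kidney namespaces stay unambiguous.
#'
#' @param labels character vector of finding labels.
#' @return data.frame with columns `organ` and `term`.
#' @keywords internal
parseFindingLabels <- function(labels) {
  parts <- regmatches(labels, regexpr(":", labels), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    .fail("finding label '%s' is not of the form 'organ:term'",
          labels[which(bad)[1L]])
  }
  organ <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  unknown <- !organ %in% c("liver", "kidney")
  if (any(unknown)) {
    .fail("unknown organ tag '%s' in finding label '%s' (expected 'liver' or 'kidney')",
          organ[which(unknown)[1L]], labels[which(unknown)[1L]])
  }
  data.frame(organ = organ, term = term, stringsAsFactors = FALSE)
}
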