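#' Study configuration
#'
#' Collects the tunable parameters of the prediction pipeline in one validated
#' list. Defaults are the package's standing choices; see the methods vignette
#' for the rationale behind each.
#'
#' @param signature_fraction fraction of the gene universe kept as a
#'   signature, ranked by increasing t-test p-value; default 0.05 (top 5%).
#' @param knn_k neighbours per KNN sub-model; default 5 (odd, so neighbour
#'   votes cannot tie 50/50).
#' @param n_submodels jackknife sub-models per finding; default 25.
#' @param control_subset_size controls per jackknife sample: a positive
#'   integer, or `"balanced"` (default) for one control per case — the
#'   standard undersampling remedy for class imbalance.
#' @param cv_folds folds of the drug-grouped cross-validation; default 5.
#' @param min_drugs_per_finding drug-diversity filter threshold for
#'   [filterFindings()]; default 5. Applied only when requested.
#' @param normalization_scheme similarity row normalization: `"l2"` (divide by
#'   the Euclidean norm of the row, default) or `"sum_sq"` (divide by the row
#'   sum of squares, no root).
#' @param ttest_variant `"welch"` (default, unequal variances) or `"student"`
#'   (pooled variance).
#' @param random_seed master seed; all per-finding and per-submodel seeds are
#'   derived from it deterministically.
#' @return a validated list of class `StudyConfig`.
#' @export
studyConfig <- function(signature_fraction = 0.05,
                        knn_k = 5L,
                        n_submodels = 25L,
                        control_subset_size = "balanced",
                        cv_folds = 5L,
                        min_drugs_per_finding = 5L,
                        normalization_scheme = c("l2", "sum_sq"),
                        ttest_variant = c("welch", "student"),
                        random_seed = 1L) {
  normalization_scheme <- match.arg(normalization_scheme)
  ttest_variant <- match.arg(ttest_variant)
  if (signature_fraction <= 0 || signature_fraction > 1)
    .fail("signature_fraction must lie in (0, 1]")
  if (knn_k < 1) .fail("knn_k must be a positive integer")
  if (n_submodels < 1) .fail("n_submodels must be a positive integer")
  if (!identical(control_subset_size, "balanced")) {
    if (!is.numeric(control_subset_size) || control_subset_size < 1)
      .fail("control_subset_size must be a positive integer or 'balanced'")
    control_subset_size <- as.integer(control_subset_size)
  }
  if (cv_folds < 2) .fail("cv_folds must be at least 2")
  if (min_drugs_per_finding < 0) .fail("min_drugs_per_finding must be >= 0")
  structure(list(signature_fraction = signature_fraction,
                 knn_k = as.integer(knn_k),
                 n_submodels = as.integer(n_submodels),
                 control_subset_size = control_subset_size,
                 cv_folds = as.integer(cv_folds),
                 min_drugs_per_finding = as.integer(min_drugs_per_finding),
                 normalization_scheme = normalization_scheme,
                 ttest_variant = ttest_variant,
                 random_seed = as.integer(random_seed)),
            class = "StudyConfig")
}

#' Read / write a StudyConfig as a flat YAML file
#'
#' Unknown keys are an error; missing keys fall back to the defaults of
#' [studyConfig()].
#'
#' @param path YAML file path.
#' @return for `readStudyConfig`, a `StudyConfig`; for `writeStudyConfig`,
#'   `path` invisibly.
#' @export
readStudyConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(studyConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) .fail("unknown config key '%s' in '%s'", unknown[1L], path)
  do.call(studyConfig, vals)
}

#' @rdname readStudyConfig
#' @param config a `StudyConfig` list.
#' @export
writeStudyConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
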