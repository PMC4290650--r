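test_that("drug folds are balanced partitions with no drug in two folds", {
  folds <- makeDrugFolds(paste0("d", 1:10), 5, seed = 3)
  expect_identical(sort(unname(table(folds))), rep(2L, 5),
                   ignore_attr = TRUE)
  expect_setequal(names(folds), paste0("d", 1:10))

  folds11 <- makeDrugFolds(paste0("d", 1:11), 5, seed = 3)
  expect_identical(sort(as.integer(table(folds11))), c(2L, 2L, 2L, 2L, 3L))

  expect_error(makeDrugFolds(paste0("d", 1:4), 5, seed = 1), "exceeds")
  ## duplicated drug entries collapse to the distinct set
  folds2 <- makeDrugFolds(rep(paste0("d", 1:10), each = 3), 5, seed = 3)
  expect_identical(folds2, folds)
})

test_that("chooseThreshold maximizes the geometric mean with strict > calls", {
  sep <- chooseThreshold(c(0.1, 0.1, 0.9, 0.9), c(0, 0, 1, 1))
  expect_identical(sep$gmean, 1)
  expect_identical(sep$sensitivity, 1)
  expect_identical(sep$specificity, 1)
  expect_true(sep$threshold >= 0.1 && sep$threshold < 0.9)

  ## all-identical scores: every candidate has gmean 0; lowest returned
  flat <- chooseThreshold(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_identical(flat$gmean, 0)
  expect_identical(flat$threshold, -0.5)

  expect_error(chooseThreshold(1:4, c(1, 1, 1, 1)), "positive and")
})

test_that("chooseThreshold matches the exhaustive candidate-scan oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- 200
    scores <- round(runif(n), 2)  # induce ties
    labels <- rbinom(n, 1, 0.3)
    if (!any(labels == 1) || !any(labels == 0)) next
    got <- chooseThreshold(scores, labels)
    expect_equal(got$gmean, bruteBestGmean(scores, labels), tolerance = 1e-12)
    ## achieved gmean dominates every candidate, including the chosen one
    expect_equal(got$gmean,
                 sqrt(mean(scores[labels == 1] > got$threshold) *
                        mean(scores[labels == 0] <= got$threshold)),
                 tolerance = 1e-12)
  }
})

test_that("computeAUC is the Mann-Whitney statistic with half-credit ties", {
  expect_identical(computeAUC(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(computeAUC(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_error(computeAUC(1:3, c(1, 1, 1)), "both classes")

  set.seed(15)
  for (i in 1:100) {
    scores <- round(rnorm(60), 1)
    labels <- rbinom(60, 1, 0.4)
    if (!any(labels == 1) || !any(labels == 0)) next
    expect_equal(computeAUC(scores, labels), bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(16)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.5)
  base <- computeAUC(scores, labels)
  expect_equal(computeAUC(exp(scores), labels), base, tolerance = 1e-12)
  expect_equal(computeAUC(3 * scores - 7, labels), base, tolerance = 1e-12)
})

test_that("computeAUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(computeAUC(scores, labels), ref, tolerance = 1e-10)
})

test_that("rocCoordinates spans (0,0) to (1,1) and is monotone", {
  set.seed(18)
  roc <- rocCoordinates(rnorm(50), rbinom(50, 1, 0.5))
  expect_identical(roc$fpr[1], 0)
  expect_identical(roc$tpr[1], 0)
  expect_identical(roc$fpr[nrow(roc)], 1)
  expect_identical(roc$tpr[nrow(roc)], 1)
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$tpr))
})

test_that("cross-validation respects drug grouping and covers each sample once", {
  study <- tinyStudy(seed = 55, n_drugs = 10)
  cfg <- studyConfig(cv_folds = 5, signature_fraction = 0.1, n_submodels = 5)
  report <- runCrossValidation(study, cfg)

  drugs <- sampleDrugs(study)
  ## every drug in exactly one fold
  expect_setequal(names(report$folds), unique(drugs))
  ## union of test folds covers each sample exactly once per finding/scorer
  pps <- report$scores[report$scores$scorer == "PPS" &
                         report$scores$finding == findingNames(study)[1], ]
  expect_setequal(pps$sample_id, colnames(study))
  expect_identical(anyDuplicated(pps$sample_id), 0L)
  ## no test sample's drug ever occurs in its training side
  for (f in seq_len(cfg$cv_folds)) {
    testDrugs <- names(report$folds)[report$folds == f]
    sub <- report$scores[report$scores$fold == f, ]
    expect_true(all(drugs[sub$sample_id] %in% testDrugs))
  }
  expect_true(all(report$summary$sensitivity >= 0 & report$summary$sensitivity <= 1))
  expect_true(all(report$summary$auc >= 0 & report$summary$auc <= 1))
})

test_that("cross-validation is deterministic given the seed", {
  study <- tinyStudy(seed = 56)
  cfg <- studyConfig(cv_folds = 3, signature_fraction = 0.1, n_submodels = 5,
                     random_seed = 99)
  r1 <- runCrossValidation(study, cfg)
  r2 <- runCrossValidation(study, cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$scores, r2$scores)
})

test_that("identity similarity collapses IPS metrics onto PPS metrics", {
  study <- tinyStudy(seed = 57)
  cfg <- studyConfig(cv_folds = 3, signature_fraction = 0.1, n_submodels = 5)
  report <- runCrossValidation(study, cfg, similarity = "identity")
  s <- report$summary
  for (f in unique(s$finding)) {
    pps <- s[s$finding == f & s$scorer == "PPS", ]
    ips <- s[s$finding == f & s$scorer == "IPS", ]
    expect_identical(ips$sensitivity, pps$sensitivity)
    expect_identical(ips$specificity, pps$specificity)
    expect_identical(ips$auc, pps$auc)
  }
})

test_that("per-fold manifests show refitting: signatures and similarities differ", {
  study <- tinyStudy(seed = 58, n_drugs = 10, n_genes = 200)
  cfg <- studyConfig(cv_folds = 5, signature_fraction = 0.05, n_submodels = 5)
  report <- runCrossValidation(study, cfg)
  sigs <- lapply(report$manifest, `[[`, "signature_genes")
  sims <- lapply(report$manifest, `[[`, "similarity")
  ## at least one pair of folds differs in selected genes and in S
  expect_gt(length(unique(lapply(sigs, unlist))), 1L)
  expect_gt(length(unique(lapply(sims, c))), 1L)
  expect_identical(length(report$manifest), 5L)
})
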