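test_that("jackknife samples contain all cases and honour the subset size", {
  cases <- sprintf("case%02d", 1:5)
  controls <- sprintf("ctl%03d", 1:100)
  draws <- drawJackknifeSamples(cases, controls, n = 10, subsetSize = 5,
                                seed = 123)
  expect_length(draws, 10L)
  for (d in draws) {
    expect_identical(d$case_ids, cases)
    expect_length(d$control_ids, 5L)
    expect_false(anyDuplicated(d$control_ids) > 0)
    expect_true(all(d$control_ids %in% controls))
  }
  again <- drawJackknifeSamples(cases, controls, 10, 5, seed = 123)
  expect_identical(draws, again)
  expect_error(drawJackknifeSamples(cases, controls[1:3], 2, 5, 1), "exceeds")
})

test_that("control inclusion frequency matches the sampling fraction", {
  controls <- sprintf("ctl%03d", 1:100)
  draws <- drawJackknifeSamples("case1", controls, n = 1000, subsetSize = 10,
                                seed = 77)
  freq <- table(factor(unlist(lapply(draws, `[[`, "control_ids")),
                       levels = controls)) / 1000
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(freq - 0.1) <= 3 * se + 1e-12))
})

test_that("knnScore matches the brute-force all-pairs oracle", {
  set.seed(5)
  train <- matrix(rnorm(30 * 4), 30, 4,
                  dimnames = list(sprintf("t%02d", 1:30), NULL))
  labels <- setNames(rbinom(30, 1, 0.4), rownames(train))
  query <- matrix(rnorm(50 * 4), 50, 4)
  got <- knnScore(train, labels, query, k = 5)
  expect_equal(unname(got), unname(bruteKnnScore(train, labels, query, 5)),
               tolerance = 1e-12)
})

test_that("knnScore hits the [0,1] endpoints on separated clusters", {
  train <- rbind(matrix(10, 5, 2), matrix(-10, 5, 2))
  rownames(train) <- sprintf("t%02d", 1:10)
  labels <- setNames(c(rep(1, 5), rep(0, 5)), rownames(train))
  expect_identical(unname(knnScore(train, labels, c(10, 10), k = 5)), 1)
  expect_identical(unname(knnScore(train, labels, c(-10, -10), k = 5)), 0)
  expect_error(knnScore(train, labels, c(1, 2, 3), k = 5), "features")
  expect_error(knnScore(train, labels, c(1, 2), k = 11), "exceeds")
})

test_that("distance ties at the k-th neighbour resolve to the lower sample id", {
  train <- matrix(c(0, 1, 1, 2), 4, 1,
                  dimnames = list(c("s4", "s1", "s3", "s2"), NULL))
  labels <- setNames(c(0, 1, 0, 1), rownames(train))
  ## query 0: distances 0,1,1,2 -> neighbours s4 then tie(s1,s3) -> s1 wins
  expect_identical(unname(knnScore(train, labels, 0, k = 2)), 0.5)
})

test_that("PPS is the mean of sub-model scores and is order-invariant", {
  study <- tinyStudy(seed = 21)
  cfg <- studyConfig(n_submodels = 7, knn_k = 3, signature_fraction = 0.1)
  occ <- occurrence(study)
  model <- trainPathologyModel(exprValues(study),
                               setNames(occ[, 1], rownames(occ)),
                               cfg, finding = colnames(occ)[1])
  expr <- exprValues(study)[1:10, ]
  sub <- vapply(seq_along(model@submodels),
                function(j) submodelScore(model, j, expr), numeric(10))
  expect_equal(unname(predictPPS(model, expr)), unname(rowMeans(sub)),
               tolerance = 1e-12)
  expect_true(all(predictPPS(model, expr) >= 0 &
                    predictPPS(model, expr) <= 1))

  ## permuting sub-models leaves PPS unchanged
  perm <- model
  perm@submodels <- model@submodels[c(4, 1, 7, 2, 6, 3, 5)]
  expect_equal(predictPPS(perm, expr), predictPPS(model, expr),
               tolerance = 1e-12)

  ## single sample convenience wrapper agrees
  expect_equal(computePPS(model, exprValues(study)[3, model@signature@geneIds]),
               unname(predictPPS(model, expr)[3]), tolerance = 1e-12)
})

test_that("a single-submodel ensemble collapses to its sub-model", {
  study <- tinyStudy(seed = 4)
  cfg <- studyConfig(n_submodels = 1, knn_k = 3, signature_fraction = 0.1)
  occ <- occurrence(study)
  model <- trainPathologyModel(exprValues(study),
                               setNames(occ[, 1], rownames(occ)), cfg,
                               finding = colnames(occ)[1])
  expr <- exprValues(study)[1:8, ]
  expect_equal(predictPPS(model, expr),
               submodelScore(model, 1, expr), tolerance = 1e-12)
})

test_that("balanced subsetting gives every sub-model a 1:1 class ratio", {
  study <- tinyStudy(seed = 13)
  occ <- occurrence(study)
  col <- setNames(occ[, 1], rownames(occ))
  nCases <- sum(col)
  model <- trainPathologyModel(exprValues(study), col,
                               studyConfig(signature_fraction = 0.1),
                               finding = colnames(occ)[1])
  for (sm in model@submodels) {
    expect_length(sm$case_ids, nCases)
    expect_length(sm$control_ids, nCases)
  }
})

test_that("untrainable findings raise informative errors", {
  expr <- tinyExpr(8, 5)
  ids <- rownames(expr)
  cfg <- studyConfig(signature_fraction = 0.5, knn_k = 3)
  expect_error(trainPathologyModel(expr, setNames(rep(0, 8), ids), cfg,
                                   finding = "liver:X"),
               "no case samples")
  expect_error(trainPathologyModel(expr, setNames(c(1, rep(0, 7)), ids), cfg,
                                   finding = "liver:X"),
               "fewer than 2 case")
})

test_that("trained model separates held-out cases from controls on planted signal", {
  design <- simulationDesign(n_drugs = 12, samples_per_drug = 8,
                             n_genes = 200,
                             findings = c("liver:Necrosis", "kidney:Necrosis"),
                             mechanisms = 2, signature_size = 15,
                             prevalence_target = 0.25, effect_size = 2,
                             seed = 31)
  study <- simulateStudy(design)
  expr <- exprValues(study)
  occ <- occurrence(study)
  trainIds <- rownames(expr)[1:64]
  testIds <- setdiff(rownames(expr), trainIds)
  model <- trainPathologyModel(expr[trainIds, ],
                               setNames(occ[trainIds, 1], trainIds),
                               studyConfig(signature_fraction = 0.1),
                               finding = colnames(occ)[1])
  pps <- predictPPS(model, expr[testIds, ])
  lab <- occ[testIds, 1]
  expect_gt(mean(pps[lab == 1]), mean(pps[lab == 0]))
})
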