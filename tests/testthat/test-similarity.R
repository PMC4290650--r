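test_that("jaccardSimilarity counts N11/(N01+N10+N11)", {
  expect_equal(jaccardSimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  x <- c(1, 0, 1, 0, 1)
  expect_identical(jaccardSimilarity(x, x), 1)
  expect_identical(jaccardSimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_identical(jaccardSimilarity(c(0, 0), c(0, 0)), 0)
  expect_error(jaccardSimilarity(c(1, 0), c(1, 0, 1)), "length")
  expect_error(jaccardSimilarity(c(1, 2), c(1, 0)), "binary")
})

test_that("jaccardSimilarity matches the counting oracle on random pairs", {
  set.seed(8)
  for (i in 1:100) {
    x <- rbinom(200, 1, runif(1, 0.05, 0.5))
    y <- rbinom(200, 1, runif(1, 0.05, 0.5))
    expect_identical(jaccardSimilarity(x, y), bruteJaccard(x, y))
  }
})

test_that("jaccard is symmetric and ignores co-absent samples", {
  set.seed(12)
  x <- rbinom(50, 1, 0.3); y <- rbinom(50, 1, 0.3)
  expect_identical(jaccardSimilarity(x, y), jaccardSimilarity(y, x))
  ## appending samples where neither occurs changes nothing
  expect_identical(jaccardSimilarity(c(x, 0, 0, 0), c(y, 0, 0, 0)),
                   jaccardSimilarity(x, y))
  ## simultaneous permutation changes nothing
  p <- sample(50)
  expect_identical(jaccardSimilarity(x[p], y[p]), jaccardSimilarity(x, y))
})

test_that("pathologySimilarity composes pairwise jaccard over all columns", {
  set.seed(19)
  occ <- matrix(rbinom(600, 1, 0.25), 100, 6,
                dimnames = list(NULL, sprintf("liver:F%d", 1:6)))
  S <- pathologySimilarity(occ)
  expect_identical(S, t(S))
  for (i in 1:6) for (j in 1:6) {
    if (i == j) expect_identical(S[i, j], 1)
    else expect_identical(S[i, j], jaccardSimilarity(occ[, i], occ[, j]))
  }

  ## identical columns -> off-diagonal 1; orthogonal columns -> 0
  twin <- cbind(occ[, 1], occ[, 1])
  expect_identical(pathologySimilarity(twin)[1, 2], 1)
  orth <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_identical(pathologySimilarity(orth)[1, 2], 0)

  ## all-zero column: off-diagonals 0, diagonal forced to 1
  zero <- cbind(occ[, 1], 0)
  Sz <- pathologySimilarity(zero)
  expect_identical(Sz[2, 2], 1)
  expect_identical(Sz[1, 2], 0)
})

test_that("l2 normalization makes every row unit length", {
  set.seed(23)
  occ <- matrix(rbinom(500, 1, 0.3), 100, 5,
                dimnames = list(NULL, sprintf("liver:F%d", 1:5)))
  N <- normalizeSimilarity(pathologySimilarity(occ))
  expect_equal(unname(sqrt(rowSums(N^2))), rep(1, 5), tolerance = 1e-12)

  expect_identical(normalizeSimilarity(diag(3)), diag(3))
  expect_equal(normalizeSimilarity(matrix(1, 2, 2)),
               matrix(1 / sqrt(2), 2, 2), tolerance = 1e-15)
})

test_that("row rescaling invariance holds under l2 but rows are not symmetric", {
  set.seed(2)
  S <- pathologySimilarity(matrix(rbinom(400, 1, 0.2), 100, 4,
                                  dimnames = list(NULL, sprintf("liver:F%d", 1:4))))
  N <- normalizeSimilarity(S)
  S2 <- S; S2[2, ] <- 7.5 * S2[2, ]
  expect_equal(normalizeSimilarity(S2)[2, ], N[2, ], tolerance = 1e-12)
  ## N is row-normalized, so generally asymmetric
  expect_false(isTRUE(all.equal(N, t(N))))
})

test_that("sum_sq scheme divides by the plain sum of squares", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  N <- normalizeSimilarity(S, scheme = "sum_sq")
  expect_equal(N[1, ], S[1, ] / 1.25, tolerance = 1e-15)
})

test_that("the published eosinophilic-change row normalizes as hand summation says", {
  ## 21 similarities of 'Liver Change, eosinophilic' to every finding,
  ## as printed; second entry is Liver Cellular infiltration (0.21).
  eosRow <- c(1.00, 0.21, 0.04, 0.00, 0.02, 0.08, 0.05, 0.04, 0.05, 0.04,
              0.00, 0.00, 0.00, 0.04, 0.10, 0.01, 0.02, 0.04, 0.02, 0.05,
              0.00)
  ## independent summation oracle: explicit loop, no linear algebra
  ss <- 0
  for (v in eosRow) ss <- ss + v * v
  expected <- 0.21 / sqrt(ss)
  expect_equal(expected, 0.2023256596, tolerance = 1e-9)

  ## embed the row in a symmetric 21x21 S; row normalization of row 1
  ## depends only on row 1
  S <- diag(21)
  S[1, ] <- eosRow
  S[, 1] <- eosRow
  N <- normalizeSimilarity(S)
  expect_equal(N[1, 2], expected, tolerance = 1e-12)
})

test_that("similarity matrices round-trip as labelled TSV", {
  occ <- matrix(rbinom(60, 1, 0.4), 20, 3,
                dimnames = list(NULL, c("liver:A", "liver:B", "kidney:C")))
  S <- pathologySimilarity(occ)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSimilarityMatrix(S, f)
  back <- read.delim(f, check.names = FALSE)
  expect_identical(back$finding, rownames(S))
  expect_equal(as.matrix(back[, -1]), S, tolerance = 1e-12,
               ignore_attr = TRUE)
})
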