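test_that("validationScore is the sigmoid of the log chi2 ratio", {
  expect_equal(validationScore(1, 1), 0.5)
  expect_equal(validationScore(exp(-1), 1), 1 / (1 + exp(1)))
  expect_equal(validationScore(exp(1), 1), exp(1) / (1 + exp(1)))
  ## scale invariance
  set.seed(41)
  for (i in 1:10) {
    a <- runif(1, 0.1, 10); x <- runif(1, 0.01, 5); x0 <- runif(1, 0.01, 5)
    expect_equal(validationScore(a * x, a * x0), validationScore(x, x0))
  }
  ## chi2 of exactly zero is floored, not an error
  expect_lt(validationScore(0, 1), 1e-6)
  expect_error(validationScore(1, 0), class = "ure_domain_error")
  expect_error(validationScore(-1, 1), class = "ure_domain_error")
})

test_that("ensemblePreservation is 100 iff unchanged and tracks distortion", {
  expect_equal(ensemblePreservation(rep(0.25, 4), rep(0.25, 4)), 100)
  expect_equal(ensemblePreservation(c(1, 0, 0, 0), rep(0.25, 4)), 25)
  expect_equal(ensemblePreservation(c(0.26894, 0.73106), c(0.5, 0.5)),
               89.5, tolerance = 0.1)
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    w0 <- randomWeights(n); w <- randomWeights(n)
    ep <- ensemblePreservation(w, w0)
    expect_gt(ep, 0); expect_lte(ep, 100)
    if (max(abs(w - w0)) > 1e-3) expect_lt(ep, 100)
    perm <- sample(n)
    expect_equal(ensemblePreservation(w[perm], w0[perm]), ep)
  }
})

test_that("makeFolds partitions observables when valFraction = 1/nFolds", {
  folds <- makeFolds(10, nFolds = 5, seed = 1)
  expect_length(folds, 5)
  vals <- lapply(folds, `[[`, "val")
  expect_true(all(lengths(vals) == 2))
  expect_setequal(unlist(vals), 1:10)                 # full coverage
  expect_equal(sum(lengths(vals)), 10)                # disjoint
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(union(f$train, f$val), 1:10)
  }
  expect_true(all(lengths(lapply(makeFolds(12, 4, seed = 2), `[[`, "val")) == 3))
})

test_that("makeFolds supports the 75/25 split and is seed-reproducible", {
  folds <- makeFolds(12, nFolds = 5, valFraction = 1 / 4, seed = 3)
  expect_length(folds, 5)
  expect_true(all(lengths(lapply(folds, `[[`, "val")) == 3))
  expect_identical(makeFolds(12, 5, 1 / 4, seed = 3), folds)
  expect_false(identical(makeFolds(12, 5, 1 / 4, seed = 4), folds))
  expect_error(makeFolds(1, 2), class = "ure_input_error")
  expect_error(makeFolds(4, 8), class = "ure_input_error")
})

.mkScan <- function(grid, meanVal) {
  new("ThetaScan", thetaGrid = grid,
      scores = data.frame(theta = grid, fold = 1L, trainScore = meanVal,
                          valScore = meanVal, ep = rep(50, length(grid))),
      meanTrain = meanVal, meanVal = meanVal,
      sdVal = rep(0, length(grid)), epCurve = rep(50, length(grid)),
      thetaRecommended = NA_real_, nFolds = 1L, seed = 1L)
}

test_that("selectTheta picks the validation minimum with a conservative tie-break", {
  grid <- c(0.01, 0.1, 1, 10)
  ## V-shaped curve -> vertex
  expect_equal(selectTheta(.mkScan(grid, c(0.49, 0.40, 0.45, 0.50))), 0.1)
  ## monotone decreasing into the boundary -> no recommendation
  expect_true(is.na(selectTheta(.mkScan(grid, c(0.50, 0.48, 0.45, 0.40)))))
  ## flat within tolerance -> largest theta
  expect_equal(selectTheta(.mkScan(grid, c(0.500, 0.499, 0.500, 0.501))), 10)
  ## two thetas within 1% of the minimum -> the larger one
  expect_equal(selectTheta(.mkScan(grid, c(0.49, 0.400, 0.401, 0.50))), 1)
})

test_that("cross-validation converges to 0.5 at strong regularization", {
  fx <- smallFixture(seed = 9)
  scan <- crossValidateTheta(fx$prior, fx$obs,
                             thetaGrid = defaultThetaGrid(to = 1e6,
                                                          length = 12),
                             seed = 1)
  sc <- diagnostics(scan)
  expect_true(all(sc$trainScore > 0 & sc$trainScore < 1))
  expect_true(all(sc$valScore > 0 & sc$valScore < 1))
  expect_true(all(sc$ep > 0 & sc$ep <= 100))
  ## strongest regularization: no reweighting, scores settle at 0.5
  top <- sc[sc$theta == max(sc$theta), ]
  expect_equal(mean(top$valScore), 0.5, tolerance = 0.01)
  expect_equal(mean(top$trainScore), 0.5, tolerance = 0.01)
  expect_gte(min(scan@epCurve), 0)
  ## weaker refinement preserves more of the ensemble
  expect_true(all(diff(scan@epCurve) >= -1e-6))
})

test_that("cross-validation finds improvement on a recovery fixture", {
  fx <- smallFixture(seed = 10, bins = 18)
  scan <- crossValidateTheta(fx$prior, fx$obs, seed = 1)
  expect_lt(min(scan@meanVal), 0.5)
  expect_false(is.na(thetaRecommended(scan)))
  ## bit-reproducible for a fixed seed
  scan2 <- crossValidateTheta(fx$prior, fx$obs, seed = 1)
  expect_identical(diagnostics(scan), diagnostics(scan2))
})
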