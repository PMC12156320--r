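test_that("deviationMatrix computes squared normalized deviations", {
  obs <- ObservableSet("a", "SHIFT", 1, 1, matrix(c(0, 1), ncol = 1))
  expect_equal(deviationMatrix(obs), matrix(c(1, 0), ncol = 1,
                                            dimnames = list(NULL, "a")))
  obs2 <- ObservableSet("a", "SHIFT", 2, 2, matrix(0, 1, 1))
  expect_equal(unname(drop(deviationMatrix(obs2))), 1)
  ## perfect agreement
  obs3 <- ObservableSet(c("a", "b"), "SHIFT", c(1, 2), c(1, 1),
                        cbind(rep(1, 3), rep(2, 3)))
  expect_true(all(deviationMatrix(obs3) == 0))
})

test_that("NOE handling: preconditioning gate and one-sided deviations", {
  obs <- ObservableSet("noe", "NOE_UPPER", 4, 0.5,
                       matrix(c(2, 5), ncol = 1))
  expect_error(deviationMatrix(obs), class = "ure_input_error")
  pc <- preconditionNoe(obs)
  d2 <- deviationMatrix(pc)
  ## conformer at 2 A satisfies the 4 A bound -> zero contribution;
  ## conformer at 5 A violates it -> positive contribution
  expect_equal(unname(d2[1, 1]), 0)
  expect_gt(d2[2, 1], 0)
  ## two-sided option penalizes both
  d2two <- deviationMatrix(pc, noeOneSided = FALSE)
  expect_gt(d2two[1, 1], 0)
  expect_equal(unname(d2two[2, 1]), unname(d2[2, 1]))
})

test_that("biasPotential is the half-k-weighted sum of squared deviations", {
  d2 <- matrix(c(1, 0), ncol = 1)
  expect_equal(biasPotential(0, d2), c(0, 0))
  expect_equal(biasPotential(2, d2), c(1, 0))
  expect_equal(biasPotential(c(1, 1), matrix(1, 3, 2)), rep(1, 3))
  expect_error(biasPotential(c(1, 2), d2), class = "ure_dimension_error")
})

test_that("weightsFromK reproduces the umbrella reweighting identity", {
  prior <- microPrior()
  d2 <- matrix(c(1, 0), ncol = 1)
  ## k = 0 is the exact identity
  expect_identical(weights(weightsFromK(0, prior, d2)), weights(prior))
  ## hand evaluation: logistic(1) split
  expect_equal(weights(weightsFromK(2, prior, d2)), c(0.26894, 0.73106),
               tolerance = 1e-4)
  ## a constant bias cancels in the normalization
  expect_equal(weights(weightsFromK(5, prior, matrix(c(1, 1), ncol = 1))),
               c(0.5, 0.5))
  expect_error(weightsFromK(1, c(0, 0), d2), class = "ure_input_error")
})

test_that("weightsFromK stays normalized and positive on the prior support", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(3:40, 1)
    m <- sample(1:5, 1)
    w0 <- randomWeights(n)
    w0[sample(n, 1)] <- 0                       # sparse prior
    w0 <- normalizeWeights(w0)
    d2 <- matrix(runif(n * m, 0, 9), n, m)
    k <- rnorm(m, sd = 3)
    w <- weights(weightsFromK(k, Ensemble(w0), d2))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w[w0 > 0] > 0))
    expect_true(all(w[w0 == 0] == 0))
  }
  ## extreme k must not overflow: log-sum-exp guard
  d2 <- matrix(c(4, 0, 1), ncol = 1)
  w <- weights(weightsFromK(1e4, uniformEnsemble(3), d2))
  expect_false(anyNA(w))
  expect_equal(w[2], 1, tolerance = 1e-10)
})

test_that("chi2 measures sigma-normalized misfit of ensemble averages", {
  obs <- microObs()
  ## perfect fit
  perfect <- ObservableSet("a", "SHIFT", 0.5, 1, matrix(c(0, 1), ncol = 1))
  expect_equal(chi2(c(0.5, 0.5), perfect), 0)
  ## unit residual
  expect_equal(chi2(c(1, 0), obs), 1)
  ## derived micro value at the logistic weights
  expect_equal(chi2(c(0.26894, 0.73106), obs), 0.07233, tolerance = 1e-4)
  ## an observable set cannot be empty
  expect_error(ObservableSet(character(0), character(0), numeric(0),
                             numeric(0), matrix(0, 1, 0)))
})

test_that("chi2 treats NOE upper bounds one-sided", {
  ## bound 4 A; ensemble sits at 3 A: satisfied -> no penalty
  near <- preconditionNoe(ObservableSet("noe", "NOE_UPPER", 4, 0.5,
                                        matrix(c(3, 3), ncol = 1)))
  expect_equal(chi2(c(0.5, 0.5), near), 0)
  ## ensemble at 5 A violates the bound -> penalty
  far <- preconditionNoe(ObservableSet("noe", "NOE_UPPER", 4, 0.5,
                                       matrix(c(5, 5), ncol = 1)))
  expect_gt(chi2(c(0.5, 0.5), far), 0)
  ## two-sided option penalizes the satisfied case too
  expect_gt(chi2(c(0.5, 0.5), near, noeOneSided = FALSE), 0)
})

test_that("KL divergences match closed forms and are non-negative", {
  u2 <- c(0.5, 0.5)
  q <- c(0.26894, 0.73106)
  expect_equal(klForward(u2, u2), 0)
  expect_equal(klForward(u2, q), 0.1201, tolerance = 1e-3)
  expect_equal(klForward(c(1, 0), u2), log(2))
  expect_equal(klReverse(q, u2), 0.1109, tolerance = 1e-3)
  expect_equal(klReverse(c(1, 0, 0, 0), rep(0.25, 4)), log(4))
  expect_equal(klReverse(u2, u2), 0)
  ## missing support in the proposal
  expect_equal(klForward(u2, c(1, 0)), Inf)
  set.seed(31)
  for (i in 1:15) {
    n <- sample(2:25, 1)
    p <- randomWeights(n); q2 <- randomWeights(n)
    expect_gte(klForward(p, q2), 0)
    expect_gte(klReverse(q2, p), 0)
  }
})

test_that("ureCost adds the theta-scaled divergence to chi2", {
  prior <- microPrior()
  obs <- microObs()
  ## k = 0: cost is the initial chi2
  expect_equal(ureCost(0, 1, prior, obs), chi2(prior, obs))
  ## theta = 1 at k = 2: sum of the two derived micro values
  expect_equal(ureCost(2, 1, prior, obs), 0.1924, tolerance = 1e-3)
  expect_error(ureCost(0, -1, prior, obs), class = "ure_input_error")
})
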