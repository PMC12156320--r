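test_that("karplusJ3 evaluates the Karplus relation", {
  expect_equal(karplusJ3(0, karplusCoefficients(1, 0, 0)), 1)
  expect_equal(karplusJ3(60, karplusCoefficients(6.51, -1.76, 1.60)),
               2.3475, tolerance = 1e-4)
  ## periodic in 360 degrees
  cf <- karplusCoefficients(6.51, -1.76, 1.60, delta = -60)
  ang <- seq(-180, 180, by = 30)
  expect_equal(karplusJ3(ang, cf), karplusJ3(ang + 360, cf))
})

test_that("the default grid system has 36x36 Boltzmann-weighted bins", {
  g <- makeGridSystem(seed = 1)
  expect_equal(nConformers(priorEnsemble(g)), 1296)
  expect_equal(nObservables(observables(g)), 12)
  expect_equal(sum(weights(priorEnsemble(g))), 1, tolerance = 1e-12)
  ## bin centers at -175, -165, ..., +175
  expect_equal(sort(unique(g@phiCenters)), seq(-175, 175, by = 10))
  ## two couplings + ten shift-like observables
  expect_equal(obsClass(observables(g)),
               c(rep("JCOUPLING", 2), rep("SHIFT", 10)))
  ## baseline is self-consistent: exp values are the prior averages
  expect_equal(chi2(priorEnsemble(g), observables(g)), 0, tolerance = 1e-20)
})

test_that("a flat surface gives the equipotential prior", {
  g <- makeGridSystem(basins = list(c(0, 0, 0, 30)), seed = 1)
  expect_equal(weights(priorEnsemble(g)), rep(1 / 1296, 1296))
  expect_error(makeGridSystem(basins = list()), class = "ure_input_error")
})

test_that("one deep narrow basin concentrates the Boltzmann prior", {
  g <- makeGridSystem(basins = list(c(-60, -45, 12, 15)), seed = 1)
  w <- weights(priorEnsemble(g))
  inside <- abs(ureweight:::.angDiff(g@phiCenters, -60)) <= 45 &
    abs(ureweight:::.angDiff(g@psiCenters, -45)) <= 45
  expect_gt(sum(w[inside]), 0.99)
})

test_that("deeper basins dominate shallower ones of equal width", {
  g <- makeGridSystem(basins = list(c(-120, 120, 5, 20), c(60, -60, 2, 20)),
                      seed = 1)
  w <- weights(priorEnsemble(g))
  nearDeep <- abs(ureweight:::.angDiff(g@phiCenters, -120)) <= 40 &
    abs(ureweight:::.angDiff(g@psiCenters, 120)) <= 40
  nearShallow <- abs(ureweight:::.angDiff(g@phiCenters, 60)) <= 40 &
    abs(ureweight:::.angDiff(g@psiCenters, -60)) <= 40
  expect_gt(sum(w[nearDeep]), sum(w[nearShallow]))
})

test_that("recovery fixtures are self-consistent and reproducible", {
  g <- makeGridSystem(seed = 2, phiBins = 12, psiBins = 12)
  ## k = 0 without noise: experimental values equal prior averages
  fx0 <- makeRecoveryFixture(g, kTrue = rep(0, 12), noiseSd = 0, seed = 1)
  expect_equal(chi2(fx0$prior, fx0$obs), 0, tolerance = 1e-20)
  ## nonzero k without noise: detectable bias
  fx1 <- makeRecoveryFixture(g, kTrue = rep(1, 12), noiseSd = 0, seed = 1)
  expect_gt(chi2(fx1$prior, fx1$obs), 0)
  ## same seed, same fixture
  fxA <- makeRecoveryFixture(g, noiseSd = 0.2, seed = 7)
  fxB <- makeRecoveryFixture(g, noiseSd = 0.2, seed = 7)
  expect_identical(expValues(fxA$obs), expValues(fxB$obs))
  expect_identical(fxA$kTrue, fxB$kTrue)
  expect_false(identical(expValues(fxA$obs),
                         expValues(makeRecoveryFixture(g, noiseSd = 0.2,
                                                       seed = 8)$obs)))
})

test_that("the three-state classifier partitions conformers", {
  ## unfolded needs BOTH thresholds exceeded
  expect_equal(classifyChignolinState("bPR", 7.0, 3.5), "unfolded")
  expect_equal(classifyChignolinState("aL", 7.0, 3.5), "unfolded")
  expect_equal(classifyChignolinState("bPR", 5.0, 1.0), "native")
  expect_equal(classifyChignolinState("aL", 5.0, 1.0), "misfolded")
  expect_equal(classifyChignolinState("bPR", 7.0, 2.0), "native")
  expect_equal(classifyChignolinState("aL", 6.0, 3.5), "misfolded")
  ## configurable mapping
  expect_equal(classifyChignolinState("aL", 5, 1,
                                      mapping = c(aL = "native",
                                                  bPR = "misfolded")),
               "native")
  expect_error(classifyChignolinState("pp2", 5, 1),
               class = "ure_input_error")
  expect_error(classifyChignolinState("bPR", -1, 1),
               class = "ure_domain_error")
  ## vectorized: exactly one state per conformer
  set.seed(5)
  n <- 200
  states <- classifyChignolinState(sample(c("bPR", "aL"), n, TRUE),
                                   runif(n, 4, 9), runif(n, 0, 6))
  expect_length(states, n)
  expect_true(all(states %in% c("native", "misfolded", "unfolded")))
})
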