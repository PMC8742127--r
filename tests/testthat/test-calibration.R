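test_that("exact lines are recovered perfectly", {
  d <- seq(4, 14, 2)
  fit <- fitKnormRegression(d, 2 + 0.5 * d)
  expect_equal(beta0(fit), 2, tolerance = 1e-12)
  expect_equal(beta1(fit), 0.5, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1)
  expect_equal(fit@nMissing, 0L)
})

test_that("missing K_norm values are skipped and counted", {
  d <- seq(4, 14, 2)
  k <- 1 + 0.3 * d
  k[c(2, 5)] <- NA                     # two missing of six
  fit <- fitKnormRegression(d, k)
  expect_equal(fit@nUsed, 4L)
  expect_equal(fit@nMissing, 2L)
  expect_equal(beta1(fit), 0.3, tolerance = 1e-12)
  expect_error(fitKnormRegression(d, c(1, NA, NA, NA, NA, NA)),
               "two non-missing")
})

test_that("noisy fits equal the closed-form normal-equations oracle", {
  set.seed(20)
  for (i in 1:20) {
    x <- runif(15, 2, 20)
    y <- rnorm(15, 1 + 0.4 * x, 0.3)
    fit <- fitKnormRegression(x, y)
    oracle <- olsOracle(x, y)
    expect_equal(beta0(fit), oracle[1], tolerance = 1e-10)
    expect_equal(beta1(fit), oracle[2], tolerance = 1e-10)
  }
})

test_that("reference calibration surfaces evaluate correctly", {
  s1 <- beta1Surface()
  expect_equal(evalCalibSurface(s1, 0, 0), 1.251 + 1.046 + 0.1389)
  expect_equal(surfaceAsymptote(s1), 0.1389)
  expect_equal(evalCalibSurface(s1, 1e6, 1e6), 0.1389)
  s0 <- beta0Surface()
  expect_equal(surfaceAsymptote(s0), -0.4093)
  expect_equal(evalCalibSurface(s0, 2, 3),
               -3.803 * exp(-0.4382 * 2) - 2.356 * exp(-0.6406 * 3) -
                 0.4093)
})

test_that("surface fitting recovers both reference coefficient sets", {
  g <- expand.grid(x1 = seq(0.5, 6, length.out = 20),
                   x2 = seq(0.5, 6, length.out = 20))
  for (ref in list(beta1Surface(), beta0Surface())) {
    z <- evalCalibSurface(ref, g$x1, g$x2)
    fit <- fitAnalyticSurface(g$x1, g$x2, z, response = ref@response)
    expect_equal(fit@a1, ref@a1, tolerance = 1e-3)
    expect_equal(fit@b1, ref@b1, tolerance = 1e-3)
    expect_equal(fit@a2, ref@a2, tolerance = 1e-3)
    expect_equal(fit@b2, ref@b2, tolerance = 1e-3)
    expect_equal(fit@c, ref@c, tolerance = 1e-3)
    # exactness on noise-free self-generated data
    expect_lt(sum((evalCalibSurface(fit, g$x1, g$x2) - z)^2), 1e-6)
  }
})

test_that("constant responses degenerate to the constant surface", {
  g <- expand.grid(x1 = seq(1, 5, length.out = 15),
                   x2 = seq(1, 5, length.out = 15))
  fit <- fitAnalyticSurface(g$x1, g$x2, rep(1.7, nrow(g)))
  expect_lt(abs(fit@a1), 1e-6)
  expect_lt(abs(fit@a2), 1e-6)
  expect_equal(fit@c, 1.7, tolerance = 1e-9)
  expect_error(fitAnalyticSurface(1:5, 1:5, 1:5), "10 points")
})

test_that("planted single-predictor signal is ranked first", {
  set.seed(30)
  x <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  y <- 2 * x[[7]] + rnorm(200, 0, 0.05)
  hits <- vapply(1:10, function(s) {
    rankPredictors(x, y, nTrees = 200, seed = s)$predictor[1] == "V7"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("pure-noise responses produce no dominant importance", {
  set.seed(31)
  x <- as.data.frame(matrix(rnorm(150 * 12), 150, 12))
  y <- rnorm(150)
  imp <- rankPredictors(x, y, nTrees = 300, seed = 1)
  # no score may dominate: top importance within the null spread
  expect_lt(imp$importance[1],
            mean(imp$importance) + 6 * sd(imp$importance) + 1e-9)
  expect_warning(rankPredictors(x, rep(1, 150), nTrees = 50),
                 "constant response")
})

test_that("importance ranking is invariant to affine predictor rescaling", {
  set.seed(32)
  x <- as.data.frame(matrix(rnorm(150 * 6), 150, 6))
  y <- 1.5 * x[[2]] - x[[5]] + rnorm(150, 0, 0.1)
  r1 <- rankPredictors(x, y, nTrees = 300, seed = 9)
  x2 <- x
  x2[[2]] <- 100 * x2[[2]] - 7
  r2 <- rankPredictors(x2, y, nTrees = 300, seed = 9)
  expect_identical(r1$predictor[1:2], r2$predictor[1:2])
})

test_that("tuned ensembles learn noise-free responses and not constants", {
  set.seed(33)
  x <- data.frame(x1 = runif(120, 0.5, 6), x2 = runif(120, 0.5, 6))
  y <- evalCalibSurface(beta1Surface(), x$x1, x$x2)
  idx <- sample(120, 90)
  m <- tuneAndTrain(x[idx, ], y[idx], nCycles = 300, cvCycles = 60,
                    seed = 2)
  pred <- predictEnsemble(m, x[-idx, ])
  r2 <- 1 - sum((pred - y[-idx])^2) / sum((y[-idx] - mean(y[-idx]))^2)
  expect_gt(r2, 0.95)
  # constant response: no spurious skill
  mc <- tuneAndTrain(x[idx, ], rep(2, 90), nCycles = 50, cvCycles = 30,
                     seed = 3)
  predc <- predictEnsemble(mc, x[-idx, ])
  expect_lt(max(abs(predc - 2)), 0.02)
})

test_that("probe grids cover the central band with the requested density", {
  x <- data.frame(x1 = c(0, runif(50, 0, 10), 10),
                  x2 = c(2, runif(50, 2, 4), 4))
  m <- trainEnsembleModel(x, x$x1 + x$x2, method = "bagging", nCycles = 30,
                          seed = 1)
  probe <- probeModelSurface(m, x$x1, x$x2, n = 200)
  expect_equal(nrow(probe), 200 * 200)
  expect_equal(range(probe$x1), c(2, 8))
  expect_equal(range(probe$x2), c(2.4, 3.6))
  expect_equal(length(unique(probe$x1)), 200)
  # constant model gives a constant probe grid
  mconst <- trainEnsembleModel(x, rep(5, nrow(x)), method = "bagging",
                               nCycles = 20, seed = 1)
  expect_lt(diff(range(probeModelSurface(mconst, x$x1, x$x2, n = 20)$z)),
            1e-9)
})
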