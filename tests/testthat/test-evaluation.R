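test_that("the calibration inversion is an exact algebraic identity", {
  set.seed(40)
  b0 <- rnorm(200)
  b1 <- runif(200, 0.1, 2)
  d <- runif(200, 2, 20)
  k <- b0 + b1 * d
  expect_lt(max(abs(predictDiameter(k, b0, b1) - d)), 1e-12)
  expect_equal(predictDiameter(0.7, beta0 = 0.7, beta1 = 0.4), 0)
  expect_error(predictDiameter(1, 0, 1e-12), "degenerate")
})

test_that("predictions are equivariant under joint rescaling", {
  k <- c(1.2, 2.4); b0 <- 0.3; b1 <- 0.21
  for (c in c(0.1, 3, 50))
    expect_equal(predictDiameter(c * k, c * b0, c * b1),
                 predictDiameter(k, b0, b1), tolerance = 1e-12)
})

test_that("two-point summary cells match hand-computed statistics", {
  rec <- data.frame(repeat_id = 1, method = "fixed", set_id = 1:2,
                    true_diameter = 4, predicted = c(4, 6))
  s <- summarizeRecords(rec, pool = TRUE)
  expect_equal(s$mean, 5)
  expect_equal(s$median, 5)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$cv, 100 * sqrt(2) / 5)
  # identical records: zero dispersion
  rec2 <- data.frame(repeat_id = 1, method = "rf", set_id = 1:3,
                     true_diameter = 8, predicted = rep(8, 3))
  s2 <- summarizeRecords(rec2, pool = TRUE)
  expect_equal(s2$sd, 0)
  expect_equal(s2$cv, 0)
})

test_that("pooled and per-repeat means agree (linearity)", {
  set.seed(41)
  rec <- expand.grid(repeat_id = 1:5, method = "rf", set_id = 1:8,
                     true_diameter = c(4, 8))
  rec$predicted <- rec$true_diameter + rnorm(nrow(rec), 0, 0.3)
  a <- summarizeRecords(rec, pool = TRUE)
  b <- summarizeRecords(rec, pool = FALSE)
  # balanced design: mean of per-repeat means equals the pooled mean
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
})

test_that("noise-free evaluation with known surfaces predicts exactly", {
  ds <- generateCalibrationDataset(
    surrogateConfig(nPropertySets = 40, noiseSdKnorm = 0, noiseSdBeta1 = 0,
                    noiseSdBeta0 = 0, seed = 8))
  res <- runEvaluation(ds, nRepeats = 30, methods = "analytic",
                       analyticSurfaces = list(beta0 = beta0Surface(),
                                               beta1 = beta1Surface()),
                       seed = 1)
  expect_lt(max(abs(res$records$predicted - res$records$true_diameter)),
            1e-6)
  s <- res$summary
  expect_equal(s$cv, rep(0, nrow(s)), tolerance = 1e-8)
  expect_equal(nrow(s), 6L)   # one row per diameter
})

test_that("analytic-method CV decreases with the true diameter", {
  # beta noise only: a fixed absolute calibration error divided by a larger
  # signal yields a relatively smaller diameter error
  ds <- generateCalibrationDataset(
    surrogateConfig(nPropertySets = 80, noiseSdKnorm = 0, seed = 9))
  res <- runEvaluation(ds, nRepeats = 10, methods = "analytic",
                       analyticSurfaces = list(beta0 = beta0Surface(),
                                               beta1 = beta1Surface()),
                       seed = 2)
  cvs <- res$summary$cv[order(res$summary$true_diameter)]
  expect_lt(cvs[6], cvs[1])
  expect_lt(mean(diff(cvs) > 0), 0.5)   # predominantly decreasing
})

test_that("summary covers methods x diameters x indicators", {
  ds <- smallDataset(n = 30, seed = 10)
  res <- runEvaluation(ds, nRepeats = 2, nCycles = 60,
                       methods = c("analytic", "fixed"),
                       analyticSurfaces = list(beta0 = beta0Surface(),
                                               beta1 = beta1Surface()),
                       seed = 3)
  s <- res$summary
  expect_setequal(unique(s$method), c("analytic", "fixed"))
  expect_equal(nrow(s), 2 * 6)
  expect_true(all(c("mean", "median", "sd", "cv") %in% names(s)))
  overall <- attr(s, "overall")
  expect_equal(nrow(overall), 2L)
  expect_true(all(overall$cv >= 0))
})

test_that("evaluation runs end to end with trained ensembles", {
  ds <- smallDataset(n = 40, seed = 11)
  res <- runEvaluation(ds, nRepeats = 2, nCycles = 50, probeN = 25,
                       methods = c("rf", "fixed"),
                       hyperparams = list(
                         beta0 = list(method = "bagging", learnRate = NA,
                                      minLeaf = 3),
                         beta1 = list(method = "lsboost", learnRate = 0.35,
                                      minLeaf = 1)),
                       seed = 4)
  expect_setequal(unique(res$records$method), c("rf", "fixed"))
  expect_true(all(res$records$true_diameter %in% seq(4, 14, 2)))
  # identical seed reruns identically
  res2 <- runEvaluation(ds, nRepeats = 2, nCycles = 50, probeN = 25,
                        methods = c("rf", "fixed"),
                        hyperparams = res$hyperparams, seed = 4)
  expect_equal(res$records$predicted, res2$records$predicted,
               tolerance = 1e-12)
})
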