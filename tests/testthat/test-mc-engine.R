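test_that("fiber launch sampling respects core and emission cone", {
  src <- sourceSpec(50, 50, coreDiameter = 20, na = 0.35)
  ls <- sampleLaunch(1e5, src, nExternal = 1.0, seed = 1)
  r <- sqrt((ls$x - 50)^2 + (ls$y - 50)^2)
  expect_lte(max(r), 10)
  expect_lt(abs(max(acos(ls$uz)) - asin(0.35)) / asin(0.35), 0.01)
  # collimated limit
  ls0 <- sampleLaunch(1000, sourceSpec(50, 50, coreDiameter = 20,
                                       na = 1e-12), seed = 2)
  expect_true(all(ls0$uz == 1))
  # point source
  lsp <- sampleLaunch(1000, sourceSpec(50, 50, coreDiameter = 0,
                                       na = 0.35), seed = 3)
  expect_true(all(lsp$x == 50 & lsp$y == 50))
})

test_that("ballistic limit: matched index, no interactions", {
  vol <- homogeneousVolume(opticalProperties(0, 0, 0, 1, name = "void"))
  det <- simulatePhotons(vol, sourceSpec(50, 50, na = 1e-9),
                         detectorSpec(na = 0.25),
                         mcConfig(nPhotons = 5000, seed = 4))
  tl <- tallies(det)
  expect_equal(unname(tl["transmitted"]), 5000)
  expect_equal(unname(tl["detected"]), 0)
})

test_that("normal-incidence Fresnel reflectance matches the analytic value", {
  vol <- homogeneousVolume(opticalProperties(0, 0, 0, 1.4, name = "glass"))
  n <- 1e5
  det <- simulatePhotons(vol, sourceSpec(50, 50, na = 1e-9),
                         detectorSpec(na = 0.25),
                         mcConfig(nPhotons = n, seed = 5))
  R <- unname(tallies(det)["detected"]) / n
  Rtrue <- ((1.4 - 1) / (1.4 + 1))^2
  se <- sqrt(Rtrue * (1 - Rtrue) / n)
  expect_lt(abs(R - Rtrue), 3 * se)
})

test_that("weight is conserved exactly when absorption is zero", {
  vol <- homogeneousVolume(scatterProps(mua = 0, mus = 20, g = 0.8, n = 1))
  det <- simulatePhotons(vol, sourceSpec(50, 50), detectorSpec(),
                         mcConfig(nPhotons = 2e4, seed = 6))
  expect_equal(sum(tallies(det)) / det@nLaunched, 1, tolerance = 1e-12)
})

test_that("box reflectance agrees with an independent transport oracle", {
  mua <- 0.0005; mus <- 0.02; g <- 0.8  # per um
  vol <- homogeneousVolume(
    opticalProperties(mua * 1000, mus * 1000, g, 1, name = "slab"),
    dims = c(100L, 100L, 200L))
  n <- 4000
  det <- simulatePhotons(vol, sourceSpec(50, 50, coreDiameter = 0,
                                         na = 1e-9),
                         detectorSpec(na = 1),
                         mcConfig(nPhotons = n, seed = 7))
  tl <- tallies(det) / n
  engineTop <- unname(tl["detected"] + tl["top"])
  oracle <- oracleBoxMC(n, mua, mus, g, 100, 100, 200, 50, 50, seed = 8)
  # binomial-scale MC error on both estimators
  se <- sqrt(oracle["top"] * (1 - oracle["top"]) / n) * sqrt(2)
  expect_lt(abs(engineTop - unname(oracle["top"])), 3 * se)
})

test_that("Beer-law rendering is consistent with the in-flight weight", {
  vol <- homogeneousVolume(scatterProps(mua = 2, mus = 15, g = 0.7, n = 1))
  det <- simulatePhotons(vol, sourceSpec(50, 50), detectorSpec(na = 1),
                         mcConfig(nPhotons = 5000, seed = 9))
  ph <- detectedPhotons(det)
  expect_gt(nrow(ph), 50)
  rendered <- beerWeights(det)   # same absorption map as propagation
  expect_equal(rendered, ph$weight, tolerance = 1e-9)
  # pathlengths non-negative, exit directions upward and inside the cone
  expect_true(all(pathlengths(det) >= 0))
  expect_true(all(ph$uz < 0))
})

test_that("zero and closed-form absorption maps rescale contributions", {
  vol <- homogeneousVolume(scatterProps(mua = 1, mus = 10, g = 0.5, n = 1))
  det <- simulatePhotons(vol, sourceSpec(50, 50), detectorSpec(na = 1),
                         mcConfig(nPhotons = 2000, seed = 10))
  w0 <- beerWeights(det, muA = c(slab = 0, blood = 0))
  expect_equal(unname(w0), detectedPhotons(det)$rouletteFactor)
  # single medium, known pathlength: contribution = exp(-mua * L)
  L <- rowSums(pathlengths(det))
  w1 <- beerWeights(det, muA = c(slab = 1, blood = 1))
  expect_equal(w1, detectedPhotons(det)$rouletteFactor * exp(-L / 1000),
               tolerance = 1e-12)
  expect_error(renderReflectance(det, muA = c(slab = -1, blood = 0)),
               ">= 0")
})

test_that("detected reflectance is monotone in any medium's absorption", {
  vol <- buildTissueVolume(deskGeometry(capDiameter = 12))
  det <- simulatePhotons(vol, sourceSpec(63, 63), detectorSpec(),
                         mcConfig(nPhotons = 3e4, seed = 11))
  muA <- setNames(det@media$mu_a, det@media$name)
  base <- sum(imageGrid(renderReflectance(det, muA = muA)))
  for (m in c("stratum corneum", "blood")) {
    up <- muA; up[m] <- up[m] * 2
    expect_lte(sum(imageGrid(renderReflectance(det, muA = up))), base)
  }
})

test_that("identical seeds give bit-identical photon streams", {
  vol <- homogeneousVolume(scatterProps())
  run <- function() simulatePhotons(vol, sourceSpec(50, 50),
                                    detectorSpec(),
                                    mcConfig(nPhotons = 2000, seed = 77))
  a <- run(); b <- run()
  expect_identical(detectedPhotons(a), detectedPhotons(b))
  expect_identical(tallies(a), tallies(b))
})

test_that("reflectance of a homogeneous volume is symmetric about the source", {
  vol <- homogeneousVolume(scatterProps(mua = 0.2, mus = 20, g = 0.8,
                                        n = 1.0),
                           dims = c(101L, 101L, 150L))
  det <- simulatePhotons(vol, sourceSpec(50.5, 50.5), detectorSpec(na = 1),
                         mcConfig(nPhotons = 2e5, seed = 12))
  img <- imageGrid(renderReflectance(det))
  left <- img[1:50, ]
  right <- img[101:52, ]
  # chi-square on mirrored halves, coarse 10 x 10 binning
  binify <- function(m) {
    idx <- (seq_len(nrow(m)) - 1) %/% 5
    jdx <- (seq_len(ncol(m)) - 1) %/% 11
    as.vector(rowsum(t(rowsum(m, idx)), jdx))
  }
  o1 <- binify(left); o2 <- binify(right)
  keep <- (o1 + o2) > 25
  chi2 <- sum((o1[keep] - o2[keep])^2 / (o1[keep] + o2[keep]))
  expect_lt(chi2, qchisq(0.99, df = sum(keep)))
})

test_that("configuration errors are caught", {
  vol <- homogeneousVolume(scatterProps())
  expect_error(simulatePhotons(vol, sourceSpec(50, 50, na = 1.2),
                               detectorSpec(), mcConfig(nPhotons = 10)),
               "NA")
  expect_error(mcConfig(rouletteThreshold = 1.2), "roulette")
  expect_error(mcConfig(rouletteFactor = 1), "roulette")
})
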