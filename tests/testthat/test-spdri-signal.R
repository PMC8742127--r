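# small ReflectanceImage from a plain matrix
imageFromGrid <- function(m, photons = sum(m) + 1)
  new("ReflectanceImage", grid = m, pixelSize = 1,
      photonsLaunched = photons, muaUsed = numeric(), sourceXY = c(0, 0))

test_that("identical images give a unit ratio", {
  m <- matrix(runif(80 * 90, 0.5, 2), 80, 90)
  spd <- computeSPDRI(imageFromGrid(m), imageFromGrid(m), shift = c(0, 0),
                      sigma = 0)
  expect_true(all(spd@mask))
  expect_equal(spd@ratio, matrix(1, 80, 90), ignore_attr = TRUE)
})

test_that("a localized perturbation moves only nearby ratio pixels off unity", {
  set.seed(1)
  a <- matrix(1, 60, 120)
  b <- a
  b[, 55:65] <- a[, 55:65] * 1.2   # capillary-like band in y
  spd <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), shift = c(0, 0),
                      sigma = 0)
  off <- which(abs(spd@ratio - 1) > 1e-12, arr.ind = TRUE)
  expect_true(all(off[, 2] >= 55 & off[, 2] <= 65))
})

test_that("registration shift aligns the source positions", {
  # image b equals image a translated by (0, +10): after registration the
  # ratio must be 1 on the whole overlap
  a <- matrix(runif(50 * 70, 1, 2), 50, 70)
  b <- a
  b[, 11:70] <- a[, 1:60]
  spd <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), shift = c(0, 10),
                      sigma = 0)
  expect_equal(spd@ratio[, 1:60], matrix(1, 50, 60), ignore_attr = TRUE)
  expect_error(computeSPDRI(imageFromGrid(a), imageFromGrid(b),
                            shift = c(0, 100)), "shift")
  expect_error(computeSPDRI(imageFromGrid(a),
                            imageFromGrid(matrix(1, 10, 10))), "dimensions")
})

test_that("reciprocal ratios multiply to one before smoothing", {
  set.seed(2)
  a <- matrix(runif(40 * 40, 0.5, 3), 40, 40)
  b <- matrix(runif(40 * 40, 0.5, 3), 40, 40)
  ab <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), c(0, 0), sigma = 0)
  ba <- computeSPDRI(imageFromGrid(b), imageFromGrid(a), c(0, 0), sigma = 0)
  expect_equal(ab@ratio * ba@ratio, matrix(1, 40, 40),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-count pixels are masked and filled by the smoothing", {
  a <- matrix(1, 40, 60)
  b <- matrix(1, 40, 60)
  a[20, 30] <- 0
  spd0 <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), c(0, 0),
                       sigma = 0)
  expect_false(spd0@mask[20, 30])
  spd <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), c(0, 0),
                      sigma = 2)
  expect_true(spd@mask[20, 30])
  expect_equal(spd@ratio[20, 30], 1, tolerance = 1e-9)
})

test_that("presmooth and smooth-ratio agree on saturated images", {
  set.seed(3)
  a <- matrix(runif(50 * 50, 100, 110), 50, 50)
  b <- matrix(runif(50 * 50, 100, 110), 50, 50)
  s1 <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), c(0, 0), sigma = 3)
  s2 <- computeSPDRI(imageFromGrid(a), imageFromGrid(b), c(0, 0), sigma = 3,
                     method = "presmooth")
  expect_equal(s1@ratio, s2@ratio, tolerance = 5e-3)
})

test_that("profile filtering reproduces polynomials up to the filter order", {
  yy <- seq(-1, 1, length.out = 400)
  poly <- 1 + 0.5 * yy - yy^2 + 2 * yy^3 + 0.3 * yy^4 - 1.2 * yy^5
  m <- matrix(rep(poly, each = 5), nrow = 5, byrow = FALSE)
  spd <- new("SPDRIImage", ratio = m,
             mask = matrix(TRUE, 5, 400), sourceShift = c(0, 0),
             smoothingSigma = 0, pixelSize = 1)
  prof <- extractProfile(spd, x = 2, order = 5, frame = 151)
  interior <- 76:(400 - 75)
  expect_lt(max(abs(profileValues(prof)[interior] - poly[interior])), 1e-9)
  # constants are reproduced everywhere
  spd1 <- new("SPDRIImage", ratio = matrix(2, 5, 400),
              mask = matrix(TRUE, 5, 400), sourceShift = c(0, 0),
              smoothingSigma = 0, pixelSize = 1)
  expect_equal(profileValues(extractProfile(spd1, x = 2)),
               rep(2, 400), tolerance = 1e-12)
  expect_error(extractProfile(spd1, x = 2, frame = 400), "frame")
  expect_error(extractProfile(spd1, x = 2, frame = 152), "odd")
})

test_that("constant profiles yield missing K_norm entries", {
  prof <- signalProfile(rep(1, 300))
  kn <- computeKnorm(prof, c(100, 200))
  expect_true(all(kn$missing))
  expect_true(all(is.na(kn$knorm)))
  expect_error(computeKnorm(signalProfile(numeric()), 10))
})

test_that("triangular bump area matches the closed form h*w/2", {
  h <- 0.4; w <- 30
  y <- 0:399
  v <- rep(1, 400)
  ramp <- seq(0, 1, length.out = w + 1)
  v[171:201] <- 1 + h * ramp        # rise over w
  v[201:231] <- 1 + h * rev(ramp)   # fall over w
  prof <- signalProfile(v, y = y)
  kn <- computeKnorm(prof, 215)     # capillary on the descending edge
  expect_false(kn$missing)
  expect_equal(kn$maxY, 200)
  expect_lt(abs(kn$knorm - h * w / 2) / (h * w / 2), 0.02)
})

test_that("K_norm is linear in the modulation amplitude and shift-invariant", {
  base <- generateSurrogateProfile(10, capillaryY = c(300), n = 600,
                                   amplitudePerUm = 0.02)
  v0 <- profileValues(base)
  k1 <- computeKnorm(base, 300)$knorm
  for (c in c(0.25, 2, 7)) {
    scaled <- signalProfile(1 + c * (v0 - 1))
    expect_equal(computeKnorm(scaled, 300)$knorm, c * k1,
                 tolerance = 1e-6)
  }
  shifted <- signalProfile(v0 + 3.7)
  expect_equal(computeKnorm(shifted, 300)$knorm, k1, tolerance = 1e-9)
})

test_that("K_norm increases strictly with amplitude of a fixed-shape lobe", {
  amps <- seq(0.005, 0.05, length.out = 8)
  ks <- vapply(amps, function(a) {
    p <- generateSurrogateProfile(8, capillaryY = 250, amplitudePerUm = a,
                                  n = 500)
    computeKnorm(p, 250)$knorm
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  fit <- lm(ks ~ amps)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("max precedes min and both bracket the capillary position", {
  p <- generateSurrogateProfile(12, capillaryY = c(200, 350),
                                amplitudePerUm = 0.02, n = 600)
  kn <- computeKnorm(p, c(200, 350))
  expect_true(all(!kn$missing))
  expect_true(all(kn$maxY < kn$minY))
  expect_true(all(kn$maxY <= kn$y & kn$y <= kn$minY))
})

test_that("ratio images round-trip to TIFF", {
  spd <- new("SPDRIImage", ratio = matrix(runif(100), 10, 10),
             mask = matrix(TRUE, 10, 10), sourceShift = c(0, 0),
             smoothingSigma = 0, pixelSize = 1)
  path <- tempfile(fileext = ".tif")
  writeSPDRITIFF(spd, path)
  expect_true(file.exists(path))
})
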