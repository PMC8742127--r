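#' @rdname SurrogateConfig
#' @export
setClass("SurrogateConfig", representation(
  nPropertySets = "integer",
  diameters = "numeric",          # um
  beta1Surface = "AnalyticCalib",
  beta0Surface = "AnalyticCalib",
  noiseSdKnorm = "numeric",
  noiseSdBeta1 = "numeric",
  noiseSdBeta0 = "numeric",
  seed = "numeric"))

setValidity("SurrogateConfig", function(object) {
  msg <- character()
  if (object@nPropertySets < 1) msg <- c(msg, "nPropertySets must be >= 1")
  if (any(object@diameters <= 0) || is.unsorted(object@diameters,
                                                strictly = TRUE))
    msg <- c(msg, "diameters must be positive and strictly increasing")
  if (object@noiseSdKnorm < 0 || object@noiseSdBeta1 < 0 ||
      object@noiseSdBeta0 < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Surrogate study configuration
#'
#' Configures the fast statistical emulator of the Monte-Carlo study: the
#' number of optical-property sets (study default 236), the capillary
#' diameter grid (4--14 um in steps of 2), the beta0/beta1 calibration
#' surfaces driving the generative model (defaults: the published reference
#' surfaces, \code{\link{beta0Surface}}, \code{\link{beta1Surface}}), and
#' additive Gaussian noise levels. The beta-noise defaults were chosen so
#' that refitting the surfaces on surrogate data attains a fit quality near
#' the reference values (about 0.85 for beta1, 0.91 for beta0) -- a
#' documented heuristic, not a claim about real data.
#'
#' @param nPropertySets number of simulated individuals.
#' @param diameters capillary diameter grid, um.
#' @param beta1Surface,beta0Surface \code{AnalyticCalib} generative surfaces.
#' @param noiseSdKnorm additive noise SD on each K_norm value.
#' @param noiseSdBeta1,noiseSdBeta0 additive noise SD on the betas.
#' @param seed master seed of the generator.
#' @return a \code{SurrogateConfig}.
#' @aliases SurrogateConfig-class
#' @rdname SurrogateConfig
#' @export
surrogateConfig <- function(nPropertySets = 236, diameters = seq(4, 14, 2),
                            beta1Surface = NULL, beta0Surface = NULL,
                            noiseSdKnorm = 0.05, noiseSdBeta1 = 0.116,
                            noiseSdBeta0 = 0.249, seed = 1) {
  if (is.null(beta1Surface)) beta1Surface <- spdriBeta1Default()
  if (is.null(beta0Surface)) beta0Surface <- spdriBeta0Default()
  new("SurrogateConfig", nPropertySets = as.integer(nPropertySets),
      diameters = diameters, beta1Surface = beta1Surface,
      beta0Surface = beta0Surface, noiseSdKnorm = noiseSdKnorm,
      noiseSdBeta1 = noiseSdBeta1, noiseSdBeta0 = noiseSdBeta0, seed = seed)
}

setMethod("show", "SurrogateConfig", function(object) {
  cat(sprintf("SurrogateConfig: %d property sets x %d diameters (seed %g)\n",
              object@nPropertySets, length(object@diameters), object@seed))
})

#' Generate a surrogate calibration dataset
#'
#' Emulates the statistical structure of the full Monte-Carlo study in
#' seconds: for each simulated individual an optical-property set is drawn
#' by \code{\link{samplePropertySet}}, the calibration slope beta1 and
#' intercept beta0 are computed from the configured exponential surfaces of
#' the reduced scattering of the two outermost skin layers (plus Gaussian
#' noise), and one K_norm value per capillary diameter is generated from the
#' linear law \code{K_norm = beta0 + beta1 * diameter} (plus noise). Rows
#' whose noisy beta1 is not positive are flagged (\code{beta1_nonpos}) with
#' a warning.
#'
#' @param config a \code{\link{surrogateConfig}}.
#' @param base base optical properties (\code{\link{basePropertySet}}).
#' @param sigmaMu,sigmaGN perturbation SD fractions passed to the sampler.
#' @return a data.frame with one row per property set: \code{set_id},
#'   \code{seed}, the 24 predictors, \code{beta0_true}, \code{beta1_true},
#'   \code{beta1_nonpos} and one \code{knorm_<d>} column per diameter.
#'   The diameter grid is attached as \code{attr(, "diameters")}.
#' @examples
#' ds <- generateCalibrationDataset(surrogateConfig(nPropertySets = 5))
#' dim(ds)
#' @export
generateCalibrationDataset <- function(config = surrogateConfig(),
                                       base = basePropertySet(),
                                       sigmaMu = 0.30, sigmaGN = 0.03) {
  stopifnot(is(config, "SurrogateConfig"))
  n <- config@nPropertySets
  d <- config@diameters
  rows <- withSeed(config@seed, {
    lapply(seq_len(n), function(i) {
      s <- samplePropertySet(base, sigmaMu = sigmaMu, sigmaGN = sigmaGN)
      p <- predictors(s)
      x1 <- p[["stratum_corneum.mu_s_prime"]]
      x2 <- p[["epidermis.mu_s_prime"]]
      b1 <- evalCalibSurface(config@beta1Surface, x1, x2) +
        rnorm(1, 0, config@noiseSdBeta1)
      b0 <- evalCalibSurface(config@beta0Surface, x1, x2) +
        rnorm(1, 0, config@noiseSdBeta0)
      kn <- b0 + b1 * d + rnorm(length(d), 0, config@noiseSdKnorm)
      c(set_id = i, p, beta0_true = b0, beta1_true = b1,
        beta1_nonpos = as.numeric(b1 <= 0),
        setNames(kn, paste0("knorm_", d)))
    })
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (any(out$beta1_nonpos > 0))
    warning(sum(out$beta1_nonpos), " row(s) with non-positive beta1")
  attr(out, "diameters") <- d
  out
}

#' Generate a surrogate SP-DRI signal profile
#'
#' Builds a smooth baseline profile with one modulation lobe per capillary:
#' a single period of a sine (maximum first, then minimum -- the
#' characteristic SP-DRI morphology) centered on the capillary position.
#' The lobe amplitude is set so that the enclosed K_norm area equals
#' \code{amplitudePerUm * diameter}, making K_norm exactly linear in the
#' diameter in the noise-free case.
#'
#' @param diameter capillary diameter, um.
#' @param capillaryY capillary y-positions, px.
#' @param amplitudePerUm K_norm area per um of diameter (dimensionless *
#'   px / um).
#' @param baseline profile baseline level.
#' @param width lobe width (one sine period), px.
#' @param n profile length, px.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed optional RNG seed.
#' @return a \code{\link{SignalProfile}}.
#' @examples
#' p <- generateSurrogateProfile(10, capillaryY = c(300, 500))
#' computeKnorm(p, c(300, 500))
#' @export
generateSurrogateProfile <- function(diameter, capillaryY = c(272.5, 472.5,
                                                              672.5),
                                     amplitudePerUm = 0.01, baseline = 1,
                                     width = 60, n = 950, noiseSd = 0,
                                     seed = NULL) {
  stopifnot(amplitudePerUm >= 0, diameter >= 0, width > 0)
  y <- seq_len(n) - 1
  v <- rep(baseline, n)
  amp <- 2 * amplitudePerUm * diameter / width
  for (y0 in capillaryY) {
    sel <- y >= y0 - width / 2 & y <= y0 + width / 2
    v[sel] <- v[sel] + amp * sin(2 * pi * (y[sel] - y0 + width / 2) / width)
  }
  if (noiseSd > 0) v <- v + withSeed(seed, rnorm(n, 0, noiseSd))
  signalProfile(v, y = y)
}

#' Write a calibration dataset to CSV
#'
#' Column dictionary: \code{set_id}; 24 predictor columns named
#' \code{<medium>.mu_a}, \code{<medium>.mu_s_prime}, \code{<medium>.n};
#' generative \code{beta0_true}/\code{beta1_true}; \code{beta1_nonpos}
#' flag; \code{knorm_<d>} per diameter d (um). The diameter grid is stored
#' in a comment-free header-compatible way (parsed back from the knorm
#' column names).
#'
#' @param dataset a \code{\link{generateCalibrationDataset}} result.
#' @param path CSV path.
#' @return the path (write) / dataset with diameters attribute (read).
#' @export
writeCalibrationCSV <- function(dataset, path) {
  write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationCSV
#' @export
readCalibrationCSV <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  kn <- grep("^knorm_", names(out), value = TRUE)
  attr(out, "diameters") <- as.numeric(sub("^knorm_", "", kn))
  out
}
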