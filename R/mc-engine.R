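#' @rdname mcSpecs
#' @export
setClass("SourceSpec", representation(
  x = "numeric", y = "numeric",        # fiber center on the -z face, um
  coreDiameter = "numeric",            # um
  na = "numeric"))                     # numerical aperture

#' @rdname mcSpecs
#' @export
setClass("DetectorSpec", representation(
  na = "numeric",                      # numerical aperture of a single fiber
  pixelBin = "integer"))               # detector pixels per voxel edge

#' @rdname mcSpecs
#' @export
setClass("MCConfig", representation(
  nPhotons = "numeric",
  rouletteThreshold = "numeric",       # fraction of the launch weight
  rouletteFactor = "numeric",          # survival multiplier m
  nExternal = "numeric",               # refractive index outside the volume
  sideBoundary = "character",          # "open" or "mirror"
  maxSteps = "numeric",
  seed = "numeric"))

setValidity("SourceSpec", function(object) {
  if (object@coreDiameter < 0) return("coreDiameter must be >= 0")
  if (object@na <= 0) return("source NA must be > 0")
  TRUE
})
setValidity("DetectorSpec", function(object) {
  if (object@na <= 0) return("detector NA must be > 0")
  if (object@pixelBin < 1L) return("pixelBin must be >= 1")
  TRUE
})
setValidity("MCConfig", function(object) {
  msg <- character()
  if (object@nPhotons < 1) msg <- c(msg, "nPhotons must be >= 1")
  if (object@rouletteThreshold <= 0 || object@rouletteThreshold >= 1)
    msg <- c(msg, "rouletteThreshold must lie in (0, 1)")
  if (object@rouletteFactor < 2) msg <- c(msg, "rouletteFactor must be >= 2")
  if (object@nExternal < 1) msg <- c(msg, "nExternal must be >= 1")
  if (!object@sideBoundary %in% c("open", "mirror"))
    msg <- c(msg, "sideBoundary must be 'open' or 'mirror'")
  if (length(msg)) msg else TRUE
})

#' Source, detector and engine configuration
#'
#' \code{sourceSpec} models the illumination fiber: a 20 um core emitting
#' uniformly over the core face into a cone of half-angle
#' \code{asin(NA / nExternal)} about +z, located on the -z boundary.
#' \code{detectorSpec} models the detection fiber bundle covering the -z
#' face: packets exiting within the acceptance cone (NA 0.25 per fiber) are
#' recorded. \code{mcConfig} sets the photon budget, the russian-roulette
#' threshold (1% of the launch weight, survival factor m = 10), the external
#' refractive index and the RNG seed.
#'
#' @param x,y source center, um (Table-style px coordinates times voxel
#'   size).
#' @param coreDiameter fiber core diameter, um.
#' @param na numerical aperture.
#' @param pixelBin detector pixel size in voxels (coarser binning trades
#'   resolution for per-pixel photon statistics at desk scale).
#' @param nPhotons photon packets to launch.
#' @param rouletteThreshold roulette trigger as a fraction of launch weight.
#' @param rouletteFactor survival weight multiplier m.
#' @param nExternal refractive index of the external medium.
#' @param sideBoundary lateral-face behavior: \code{"open"} (packets leave
#'   and are tallied) or \code{"mirror"} (specular reflection, emulating a
#'   laterally semi-infinite tissue -- the desk-scale stand-in for the much
#'   wider full-scale volume).
#' @param maxSteps per-photon voxel-step budget (engine-error guard).
#' @param seed RNG seed in (0, 2^31) exclusive, or NULL.
#' @return specification objects used by \code{\link{simulatePhotons}}.
#' @aliases SourceSpec-class DetectorSpec-class MCConfig-class
#' @rdname mcSpecs
#' @export
sourceSpec <- function(x, y, coreDiameter = 20, na = 0.35)
  new("SourceSpec", x = x, y = y, coreDiameter = coreDiameter, na = na)

#' @rdname mcSpecs
#' @export
detectorSpec <- function(na = 0.25, pixelBin = 1L)
  new("DetectorSpec", na = na, pixelBin = as.integer(pixelBin))

#' @rdname mcSpecs
#' @export
mcConfig <- function(nPhotons = 1e6, rouletteThreshold = 0.01,
                     rouletteFactor = 10, nExternal = 1.0,
                     sideBoundary = c("open", "mirror"),
                     maxSteps = 5e7, seed = NULL)
  new("MCConfig", nPhotons = nPhotons, rouletteThreshold = rouletteThreshold,
      rouletteFactor = rouletteFactor, nExternal = nExternal,
      sideBoundary = match.arg(sideBoundary), maxSteps = maxSteps,
      seed = if (is.null(seed)) NA_real_ else seed)

#' @rdname DetectedPhotonSet
#' @export
setClass("DetectedPhotonSet", representation(
  photons = "data.frame",       # x, y, ux, uy, uz, weight, rouletteFactor
  pathlengths = "matrix",       # per-medium pathlength, um
  tallies = "numeric",
  nLaunched = "numeric",
  media = "data.frame",
  dims = "integer",
  voxelSize = "numeric",
  source = "SourceSpec",
  detector = "DetectorSpec",
  nExternal = "numeric"))

setMethod("show", "DetectedPhotonSet", function(object) {
  cat(sprintf("DetectedPhotonSet: %d detected of %g launched (%.3f%% weight)\n",
              nrow(object@photons), object@nLaunched,
              100 * object@tallies["detected"] / object@nLaunched))
})

#' @rdname DetectedPhotonSet
#' @param object a \code{DetectedPhotonSet}.
#' @export
detectedPhotons <- function(object) object@photons

#' @rdname DetectedPhotonSet
#' @export
pathlengths <- function(object) object@pathlengths

#' @rdname DetectedPhotonSet
#' @export
tallies <- function(object) object@tallies

#' Run voxel Monte-Carlo photon transport
#'
#' Launches photon packets from the source fiber into the labeled tissue
#' volume and returns the packets detected on the -z face within the
#' detector acceptance cone, together with their per-medium partial
#' pathlengths. Free paths are sampled from the local scattering
#' coefficient, deflection angles from the Henyey-Greenstein phase function,
#' refractive-index mismatches at voxel faces are handled by unpolarized
#' Fresnel reflection/Snell refraction (including total internal
#' reflection), absorption attenuates the packet weight continuously, and
#' low-weight packets undergo russian roulette. Identical seeds give
#' bit-identical photon streams; each packet owns a counter-based RNG
#' substream, so runs sharing a seed are photon-wise paired (common random
#' numbers) and a geometry change perturbs only packets whose paths meet
#' changed voxels.
#'
#' @param volume a \code{\link{buildTissueVolume}} result.
#' @param source a \code{\link{sourceSpec}}.
#' @param detector a \code{\link{detectorSpec}}.
#' @param config an \code{\link{mcConfig}}.
#' @param labels optional pre-materialized label array (to amortize
#'   \code{\link{voxelLabels}} across runs).
#' @return a \code{DetectedPhotonSet}. The \code{weight} column is the
#'   in-flight attenuated weight at exit (roulette factor included);
#'   \code{rouletteFactor} is the accumulated roulette multiplier, so
#'   \code{weight / rouletteFactor} equals the pure Beer-law factor
#'   \code{exp(-sum(mu_a * L))} of the propagation absorption map.
#' @aliases DetectedPhotonSet-class
#' @rdname DetectedPhotonSet
#' @export
simulatePhotons <- function(volume, source, detector = detectorSpec(),
                            config = mcConfig(), labels = NULL) {
  stopifnot(is(volume, "TissueVolume"), is(source, "SourceSpec"),
            is(detector, "DetectorSpec"), is(config, "MCConfig"))
  g <- volume@geometry
  if (source@x < 0 || source@x > g@dims[1] ||
      source@y < 0 || source@y > g@dims[2])
    stop("source position lies outside the volume face")
  if (is.null(labels)) labels <- voxelLabels(volume)
  media <- volume@media
  mediaMat <- cbind(media$mu_a / 1000, media$mu_s / 1000, media$g, media$n)
  seed <- if (is.na(config@seed)) floor(runif(1, 1, 2^31 - 1))
          else config@seed
  res <- .mc_simulate(
    labels = labels, dims = g@dims, voxel = g@voxelSize,
    media = mediaMat, labelMedium = volume@labelMap,
    srcX = source@x * g@voxelSize, srcY = source@y * g@voxelSize,
    coreDiam = source@coreDiameter, srcNA = source@na,
    detNA = detector@na, nExt = config@nExternal,
    nPhotons = as.integer(config@nPhotons),
    rrThreshold = config@rouletteThreshold,
    rrFactor = config@rouletteFactor, maxSteps = config@maxSteps,
    mirrorSides = config@sideBoundary == "mirror", seed = seed)
  ph <- as.data.frame(res$photons)
  paths <- res$pathlengths
  colnames(paths) <- media$name
  new("DetectedPhotonSet", photons = ph, pathlengths = paths,
      tallies = res$tallies, nLaunched = res$nLaunched, media = media,
      dims = g@dims, voxelSize = g@voxelSize, source = source,
      detector = detector, nExternal = config@nExternal)
}

#' Sample fiber launch states
#'
#' Draws launch positions and directions from the source model without
#' propagating, for verifying the emission geometry.
#'
#' @inheritParams simulatePhotons
#' @param n number of samples.
#' @param nExternal external refractive index.
#' @return a data.frame with columns x, y, z, ux, uy, uz.
#' @export
sampleLaunch <- function(n, source, nExternal = 1.0, seed = NULL) {
  stopifnot(is(source, "SourceSpec"), source@na < nExternal)
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  m <- .mc_sample_launch(as.integer(n), source@x, source@y,
                         source@coreDiameter, source@na, nExternal,
                         seed = seed)
  out <- as.data.frame(m)
  names(out) <- c("x", "y", "z", "ux", "uy", "uz")
  out
}

#' @rdname ReflectanceImage
#' @export
setClass("ReflectanceImage", representation(
  grid = "matrix",            # accumulated detected weight per (x, y) pixel
  pixelSize = "numeric",      # um
  photonsLaunched = "numeric",
  muaUsed = "numeric",        # per-medium absorption applied, mm^-1
  sourceXY = "numeric"))      # um

setValidity("ReflectanceImage", function(object) {
  if (any(object@grid < 0)) return("reflectance pixels must be >= 0")
  if (sum(object@grid) > object@photonsLaunched * (1 + 1e-9))
    return("total detected weight exceeds launched weight")
  TRUE
})

setMethod("show", "ReflectanceImage", function(object) {
  cat(sprintf("ReflectanceImage: %d x %d pixels (%g um), reflectance %.4g\n",
              nrow(object@grid), ncol(object@grid), object@pixelSize,
              sum(object@grid) / object@photonsLaunched))
})

#' @rdname ReflectanceImage
#' @param object a \code{ReflectanceImage}.
#' @export
imageGrid <- function(object) object@grid

#' Render a reflectance image by Beer-law post-processing
#'
#' Each detected packet contributes
#' \code{rouletteFactor * exp(-sum_m mu_a[m] * L[m])} at its exit pixel,
#' where \code{L} are the per-medium partial pathlengths. Because the
#' pathlengths are stored, arbitrary absorption maps can be applied to the
#' same detected photon set without re-running the transport.
#'
#' @param detected a \code{\link{simulatePhotons}} result.
#' @param muA named per-medium absorption coefficients, mm^-1 (default: the
#'   absorption map of the simulated volume).
#' @param pixelBin pixel size in voxels (default from the detector spec).
#' @return a \code{ReflectanceImage}.
#' @aliases ReflectanceImage-class
#' @rdname ReflectanceImage
#' @export
renderReflectance <- function(detected, muA = NULL, pixelBin = NULL) {
  stopifnot(is(detected, "DetectedPhotonSet"))
  if (is.null(muA)) muA <- setNames(detected@media$mu_a, detected@media$name)
  if (any(muA < 0)) stop("absorption coefficients must be >= 0")
  muA <- muA[colnames(detected@pathlengths)]
  if (anyNA(muA)) stop("muA must name every medium of the volume")
  if (is.null(pixelBin)) pixelBin <- detected@detector@pixelBin
  px <- detected@voxelSize * pixelBin
  nxp <- ceiling(detected@dims[1] / pixelBin)
  nyp <- ceiling(detected@dims[2] / pixelBin)
  grid <- matrix(0, nxp, nyp)
  ph <- detected@photons
  if (nrow(ph) > 0) {
    contrib <- ph$rouletteFactor *
      exp(-as.vector(detected@pathlengths %*% (muA / 1000)))
    i <- pmin(nxp - 1L, pmax(0L, floor(ph$x / px)))
    j <- pmin(nyp - 1L, pmax(0L, floor(ph$y / px)))
    idx <- i + nxp * j + 1
    acc <- rowsum(contrib, group = idx)
    grid[as.integer(rownames(acc))] <- acc[, 1]
  }
  new("ReflectanceImage", grid = grid, pixelSize = px,
      photonsLaunched = detected@nLaunched, muaUsed = unname(muA),
      sourceXY = c(detected@source@x, detected@source@y) *
        detected@voxelSize)
}

#' Per-photon Beer-law contributions
#'
#' The rendering weights without pixel accumulation, for consistency checks
#' and custom analyses.
#'
#' @inheritParams renderReflectance
#' @return numeric vector, one weight per detected photon.
#' @export
beerWeights <- function(detected, muA = NULL) {
  if (is.null(muA)) muA <- setNames(detected@media$mu_a, detected@media$name)
  muA <- muA[colnames(detected@pathlengths)]
  detected@photons$rouletteFactor *
    exp(-as.vector(detected@pathlengths %*% (muA / 1000)))
}

#' Write a reflectance image as 32-bit float TIFF
#'
#' @param image a \code{ReflectanceImage}.
#' @param path output path.
#' @param normalize divide by the launched photon count first.
#' @return the path, invisibly.
#' @export
writeReflectanceTIFF <- function(image, path, normalize = TRUE) {
  m <- imageGrid(image)
  if (normalize) m <- m / image@photonsLaunched
  tiff::writeTIFF(t(m), path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Persist / restore a detected photon set as CSV
#'
#' Plain-text round trip of the detected packets (exit position, direction,
#' weights, per-medium pathlengths) for archival and resumable pipelines.
#'
#' @param detected a \code{DetectedPhotonSet}.
#' @param path CSV path.
#' @return the path (write) or a data.frame (read).
#' @export
writeDetectedCSV <- function(detected, path) {
  df <- cbind(detected@photons, as.data.frame(detected@pathlengths))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
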