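#' @rdname SPDRIImage
#' @export
setClass("SPDRIImage", representation(
  ratio = "matrix",          # smoothed ratio image, a / b after registration
  mask = "matrix",           # TRUE where the ratio is valid
  sourceShift = "numeric",   # (dx, dy) px between the two source positions
  smoothingSigma = "numeric",
  pixelSize = "numeric"))

setMethod("show", "SPDRIImage", function(object) {
  cat(sprintf("SPDRIImage: %d x %d px, shift (%g, %g), sigma %g px, %.1f%% masked\n",
              nrow(object@ratio), ncol(object@ratio), object@sourceShift[1],
              object@sourceShift[2], object@smoothingSigma,
              100 * mean(!object@mask)))
})

#' @rdname SPDRIImage
#' @param object an \code{SPDRIImage}.
#' @export
ratioImage <- function(object) object@ratio

# Gaussian smoothing that ignores masked pixels (normalized convolution);
# sigma = 0 returns the input untouched.
maskedGaussianBlur <- function(m, mask, sigma) {
  if (sigma <= 0) {
    m[!mask] <- NA_real_
    return(list(values = m, mask = mask))
  }
  v <- m
  v[!mask] <- 0
  w <- matrix(as.numeric(mask), nrow(m), ncol(m))
  num <- EBImage::gblur(v, sigma = sigma, boundary = "replicate")
  den <- EBImage::gblur(w, sigma = sigma, boundary = "replicate")
  ok <- den > 1e-8
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[ok] <- num[ok] / den[ok]
  # valid wherever the kernel saw any measured pixel: gaps are filled
  list(values = out, mask = ok)
}

#' Compute the SP-DRI ratio image
#'
#' Registers two reflectance images acquired with a laterally shifted light
#' source so that the relative source positions coincide (image B is
#' translated by the source shift), divides image A pixel by pixel by the
#' translated image B on the overlapping region, and smooths the ratio with
#' a two-dimensional Gaussian kernel. Pixels where either image has zero
#' detected weight are masked and excluded from the smoothing (normalized
#' convolution). The output ratio pixel (x, y) corresponds to position
#' (x, y) of image A.
#'
#' @param imageA,imageB \code{\link{renderReflectance}} images; B's source
#'   is shifted by \code{shift} relative to A's.
#' @param shift source shift (dx, dy) in pixels of the image grid (default
#'   (0, 110): the two study source positions).
#' @param sigma Gaussian smoothing sigma in pixels (study value: 10 px for
#'   a 950 px image; scale proportionally for smaller volumes).
#' @param minSupport relative support threshold of the \code{"presmooth"}
#'   method: pixels where either smoothed image falls below
#'   \code{minSupport} times its maximum are masked (the ratio of two
#'   near-empty regions is unbounded noise).
#' @param method \code{"smooth-ratio"} divides pixel by pixel first and
#'   smooths the ratio (the reference processing order, appropriate when
#'   photon counts saturate every pixel); \code{"presmooth"} applies the
#'   same Gaussian to both registered images before dividing, which is the
#'   statistically well-defined variant when many pixels hold few or zero
#'   detected packets (desk-scale photon budgets). Both agree in the
#'   high-count limit.
#' @return an \code{SPDRIImage}.
#' @aliases SPDRIImage-class
#' @rdname SPDRIImage
#' @export
computeSPDRI <- function(imageA, imageB, shift = c(0, 110), sigma = 10,
                         method = c("smooth-ratio", "presmooth"),
                         minSupport = 1e-3) {
  method <- match.arg(method)
  a <- imageGrid(imageA)
  b <- imageGrid(imageB)
  if (!all(dim(a) == dim(b))) stop("image dimensions differ")
  shift <- as.integer(round(shift))
  if (abs(shift[1]) >= nrow(a) || abs(shift[2]) >= ncol(a))
    stop("source shift exceeds the image extent")
  # overlap of a[i, j] with b[i + dx, j + dy]
  ia <- seq(max(1, 1 - shift[1]), min(nrow(a), nrow(a) - shift[1]))
  ja <- seq(max(1, 1 - shift[2]), min(ncol(a), ncol(a) - shift[2]))
  av <- a[ia, ja, drop = FALSE]
  bv <- b[ia + shift[1], ja + shift[2], drop = FALSE]
  if (method == "smooth-ratio") {
    valid <- av > 0 & bv > 0
    ratio <- matrix(NA_real_, nrow(av), ncol(av))
    ratio[valid] <- av[valid] / bv[valid]
    sm <- maskedGaussianBlur(ratio, valid, sigma)
    vals <- sm$values
    mask <- sm$mask
  } else {
    asm <- if (sigma > 0) EBImage::gblur(av, sigma = sigma,
                                         boundary = "replicate") else av
    bsm <- if (sigma > 0) EBImage::gblur(bv, sigma = sigma,
                                         boundary = "replicate") else bv
    mask <- asm > minSupport * max(asm) & bsm > minSupport * max(bsm)
    vals <- matrix(NA_real_, nrow(av), ncol(av))
    vals[mask] <- asm[mask] / bsm[mask]
  }
  ratioFull <- matrix(NA_real_, nrow(a), ncol(a))
  maskFull <- matrix(FALSE, nrow(a), ncol(a))
  ratioFull[ia, ja] <- vals
  maskFull[ia, ja] <- mask
  new("SPDRIImage", ratio = ratioFull, mask = maskFull,
      sourceShift = as.numeric(shift),
      smoothingSigma = sigma, pixelSize = imageA@pixelSize)
}

#' @rdname SignalProfile
#' @export
setClass("SignalProfile", representation(
  x = "numeric",             # cross-section column (px)
  y = "numeric",             # y positions (px)
  values = "numeric",
  mask = "logical",          # TRUE where the value is measured (not a gap)
  savgolOrder = "numeric",
  savgolFrame = "numeric"))

setValidity("SignalProfile", function(object) {
  msg <- character()
  if (length(object@values) != length(object@y))
    msg <- c(msg, "values and y must have equal length")
  if (length(object@mask) != length(object@values))
    msg <- c(msg, "mask and values must have equal length")
  if (!is.na(object@savgolFrame) &&
      (object@savgolFrame %% 2 != 1 ||
       object@savgolFrame <= object@savgolOrder))
    msg <- c(msg, "filter frame must be odd and exceed the polynomial order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignalProfile", function(object) {
  cat(sprintf("SignalProfile at x = %g px: %d samples (%d masked)\n",
              object@x, length(object@values), sum(!object@mask)))
})

#' @rdname SignalProfile
#' @param object a \code{SignalProfile}.
#' @export
profileValues <- function(object) object@values

#' Construct a signal profile directly
#'
#' Wraps a 1-D signal (e.g. a synthetic fixture) as a \code{SignalProfile}
#' without filtering.
#'
#' @param values signal values.
#' @param y y positions, px (default 0-based index).
#' @param x nominal cross-section column.
#' @param mask validity mask.
#' @return a \code{SignalProfile}.
#' @aliases SignalProfile-class
#' @rdname SignalProfile
#' @export
signalProfile <- function(values, y = seq_along(values) - 1, x = NA_real_,
                          mask = rep(TRUE, length(values))) {
  new("SignalProfile", x = x, y = as.numeric(y), values = as.numeric(values),
      mask = mask, savgolOrder = NA_real_, savgolFrame = NA_real_)
}

#' Extract and filter a cross-section profile
#'
#' Takes the y-profile of the SP-DRI ratio image at a fixed x column (study
#' value: x = 570 px) and applies a Savitzky-Golay filter (polynomial order
#' 5, frame length 151 px at full scale; the frame scales with the image for
#' desk-scale volumes). Masked gaps are linearly interpolated before
#' filtering and re-masked afterwards.
#'
#' @param spdri an \code{\link{computeSPDRI}} image.
#' @param x 0-based cross-section column, px.
#' @param order Savitzky-Golay polynomial order.
#' @param frame Savitzky-Golay frame length, px (odd, > order).
#' @return a \code{SignalProfile}.
#' @export
extractProfile <- function(spdri, x = 570, order = 5, frame = 151) {
  stopifnot(is(spdri, "SPDRIImage"))
  col <- as.integer(round(x)) + 1L
  if (col < 1L || col > nrow(spdri@ratio))
    stop("cross-section column outside the image")
  v <- spdri@ratio[col, ]
  mask <- spdri@mask[col, ]
  if (frame %% 2 != 1 || frame <= order)
    stop("filter frame must be odd and exceed the polynomial order")
  if (frame > length(v))
    stop("filter frame exceeds the profile length; scale the frame to the volume")
  if (!any(mask)) stop("profile is fully masked")
  y <- seq_along(v) - 1
  if (any(!mask)) {
    v[!mask] <- stats::approx(y[mask], v[mask], xout = y[!mask],
                              rule = 2)$y
  }
  filtered <- signal::sgolayfilt(v, p = order, n = frame)
  new("SignalProfile", x = as.numeric(x), y = y, values = filtered,
      mask = mask, savgolOrder = order, savgolFrame = frame)
}

# local extrema with plateau handling: a maximum is a sign change + -> - of
# the forward difference (midpoint of an intervening plateau); plateaus
# reaching the profile boundary count as the adjacent extremum type, true
# boundary points never do.
profileExtrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(maxima = integer(), minima = integer()))
  s <- sign(diff(v))
  nz <- which(s != 0)
  maxima <- integer()
  minima <- integer()
  if (length(nz) == 0L) return(list(maxima = maxima, minima = minima))
  if (length(nz) > 1L) for (k in seq_len(length(nz) - 1L)) {
    p <- nz[k]; q <- nz[k + 1L]
    mid <- (p + 1L + q) %/% 2L
    if (s[p] == 1 && s[q] == -1) maxima <- c(maxima, mid)
    if (s[p] == -1 && s[q] == 1) minima <- c(minima, mid)
  }
  first <- nz[1L]; last <- nz[length(nz)]
  if (first > 1L) {  # leading plateau
    if (s[first] == -1) maxima <- c(first, maxima)
    if (s[first] == 1) minima <- c(first, minima)
  }
  if (last < n - 1L) {  # trailing plateau
    if (s[last] == -1) minima <- c(minima, last + 1L)
    if (s[last] == 1) maxima <- c(maxima, last + 1L)
  }
  list(maxima = sort(unique(maxima)), minima = sort(unique(minima)))
}

trapezoidArea <- function(y, v) {
  if (length(v) < 2L) return(0)
  sum(diff(y) * (head(v, -1) + v[-1]) / 2)
}

#' Per-capillary K_norm modulation statistic
#'
#' For each capillary y-position the local maximum preceding it and the
#' local minimum following it are located within a search window (default:
#' half the inter-capillary spacing on each side, nearest extremum to the
#' capillary wins ties). K_norm is the trapezoidal area enclosed between the
#' signal curve and the horizontal level of the local minimum, integrated
#' from the maximum to the minimum -- it grows linearly with the modulation
#' amplitude and is invariant under adding a constant to the profile.
#' Capillaries whose extrema are absent are flagged missing, not an error.
#'
#' @param profile a \code{\link{SignalProfile}}.
#' @param capillaryY sorted capillary y-positions, px.
#' @param window search half-width, px (default: half the minimum spacing
#'   between capillary positions; the full span for a single capillary).
#' @return a data.frame with one row per capillary: \code{capillary},
#'   \code{y}, \code{knorm} (dimensionless * px), \code{maxY}, \code{minY},
#'   \code{missing}.
#' @export
computeKnorm <- function(profile, capillaryY, window = NULL) {
  stopifnot(is(profile, "SignalProfile"))
  v <- profile@values
  y <- profile@y
  if (length(v) == 0L) stop("empty profile")
  if (is.unsorted(capillaryY)) stop("capillary positions must be sorted")
  if (any(capillaryY < min(y) | capillaryY > max(y)))
    stop("capillary position outside the profile span")
  if (is.null(window)) {
    window <- if (length(capillaryY) > 1L) min(diff(capillaryY)) / 2
              else diff(range(y)) / 2
  }
  ext <- profileExtrema(v)
  out <- lapply(seq_along(capillaryY), function(k) {
    y0 <- capillaryY[k]
    iMax <- ext$maxima[y[ext$maxima] >= y0 - window & y[ext$maxima] <= y0]
    iMin <- ext$minima[y[ext$minima] >= y0 & y[ext$minima] <= y0 + window]
    if (length(iMax) == 0L || length(iMin) == 0L)
      return(data.frame(capillary = k, y = y0, knorm = NA_real_,
                        maxY = NA_real_, minY = NA_real_, missing = TRUE))
    iMax <- iMax[which.min(y0 - y[iMax])]   # nearest preceding maximum
    iMin <- iMin[iMin > iMax]
    if (length(iMin) == 0L)
      return(data.frame(capillary = k, y = y0, knorm = NA_real_,
                        maxY = NA_real_, minY = NA_real_, missing = TRUE))
    iMin <- iMin[which.min(y[iMin] - y0)]   # nearest subsequent minimum
    seg <- iMax:iMin
    karea <- trapezoidArea(y[seg], v[seg] - v[iMin])
    # a non-positive area or an unmeasured (masked) window is no detection
    if (karea <= 0 || !all(profile@mask[seg]))
      return(data.frame(capillary = k, y = y0, knorm = NA_real_,
                        maxY = NA_real_, minY = NA_real_, missing = TRUE))
    data.frame(capillary = k, y = y0, knorm = karea, maxY = y[iMax],
               minY = y[iMin], missing = FALSE)
  })
  do.call(rbind, out)
}

#' Write the SP-DRI ratio image as TIFF
#'
#' @param spdri an \code{SPDRIImage}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSPDRITIFF <- function(spdri, path) {
  m <- spdri@ratio
  m[!spdri@mask] <- 0
  rng <- range(m, finite = TRUE)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  tiff::writeTIFF(t(m), path, bits.per.sample = 32L)
  invisible(path)
}
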