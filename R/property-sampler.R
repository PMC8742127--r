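#' @rdname BasePropertySet
#' @export
setClass("BasePropertySet", representation(
  media = "data.frame",            # 8 optical-property rows (7 layers + blood)
  wavelength = "numeric",          # nm
  hemoglobin = "numeric"))         # g/dl, metadata only

setValidity("BasePropertySet", function(object) {
  msg <- character()
  if (nrow(object@media) != 8L)
    msg <- c(msg, "exactly 8 media required (7 skin layers + blood)")
  v <- tryCatch(validateOpticalProperties(object@media),
                error = function(e) conditionMessage(e))
  if (is.character(v)) msg <- c(msg, v)
  if (length(msg)) msg else TRUE
})

#' Base optical-property set
#'
#' Bundles the base (unperturbed) optical properties of the eight media at
#' the illumination wavelength. The wavelength (default 424 nm, a local
#' maximum of the oxyhaemoglobin absorption spectrum) and the haemoglobin
#' concentration (15 g/dl) are metadata recording the conditions the blood
#' absorption value refers to.
#'
#' @param media 8-row optical-property table
#'   (default \code{\link{defaultMediaProperties}}).
#' @param wavelength illumination wavelength, nm.
#' @param hemoglobin haemoglobin concentration, g/dl.
#' @return a \code{BasePropertySet}.
#' @aliases BasePropertySet-class
#' @rdname BasePropertySet
#' @examples
#' basePropertySet()
#' @export
basePropertySet <- function(media = defaultMediaProperties(),
                            wavelength = 424, hemoglobin = 15) {
  new("BasePropertySet", media = media, wavelength = wavelength,
      hemoglobin = hemoglobin)
}

setMethod("show", "BasePropertySet", function(object) {
  cat("BasePropertySet:", nrow(object@media), "media at",
      object@wavelength, "nm (Hb", object@hemoglobin, "g/dl)\n")
})

#' @rdname samplePropertySet
#' @export
setClass("SampledPropertySet", representation(
  media = "data.frame",
  seed = "numeric",
  predictors = "numeric"))

setMethod("show", "SampledPropertySet", function(object) {
  cat("SampledPropertySet (seed", object@seed, "):",
      length(object@predictors), "predictors\n")
})

# one Gaussian draw per element with rejection resampling at physical bounds
drawBounded <- function(base, sigma, lower, upper) {
  out <- rnorm(length(base), mean = base, sd = sigma * base)
  bad <- which(out <= lower | out >= upper)
  tries <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean = base[bad], sd = sigma * base[bad])
    bad <- bad[out[bad] <= lower[bad] | out[bad] >= upper[bad]]
    tries <- tries + 1L
    if (tries > 1000L) stop("rejection sampling did not terminate; ",
                            "check base values against physical bounds")
  }
  out
}

#' Randomly perturbed optical-property set
#'
#' Draws every optical-property element independently from a Gaussian
#' centered on its base value, with standard deviation \code{sigmaMu} (a
#' fraction, default 30%) of the base value for mu_a and mu_s and
#' \code{sigmaGN} (default 3%) for g and n. Each element gets its own
#' deviation. Draws violating physical bounds (mu < 0, |g| >= 1, n < 1) are
#' rejection-resampled, which preserves the Gaussian shape away from the
#' bounds. mu_s and g are sampled separately and only reported combined as
#' mu_s' in the predictor reduction.
#'
#' @param base a \code{\link{basePropertySet}}.
#' @param sigmaMu fractional standard deviation for mu_a and mu_s.
#' @param sigmaGN fractional standard deviation for g and n.
#' @param seed RNG seed in (0, 2^31), exclusive; \code{NULL} uses the
#'   current RNG state.
#' @return a \code{SampledPropertySet} carrying the perturbed media table
#'   and the 24-predictor reduction (see \code{\link{reducePredictors}}).
#' @aliases SampledPropertySet-class
#' @rdname samplePropertySet
#' @examples
#' s <- samplePropertySet(basePropertySet(), seed = 42)
#' head(predictors(s))
#' @export
samplePropertySet <- function(base, sigmaMu = 0.30, sigmaGN = 0.03,
                              seed = NULL) {
  stopifnot(is(base, "BasePropertySet"),
            sigmaMu >= 0, sigmaMu < 1, sigmaGN >= 0, sigmaGN < 1)
  m <- base@media
  if (sigmaMu > 0 && any(m$mu_a <= 0 | m$mu_s <= 0))
    stop("base mu_a/mu_s must be > 0 when sigmaMu > 0")
  media <- withSeed(seed, {
    n8 <- nrow(m)
    out <- m
    out$mu_a <- drawBounded(m$mu_a, sigmaMu, rep(0, n8), rep(Inf, n8))
    out$mu_s <- drawBounded(m$mu_s, sigmaMu, rep(0, n8), rep(Inf, n8))
    out$g <- drawBounded(m$g, sigmaGN, rep(-1, n8), rep(1, n8))
    out$n <- drawBounded(m$n, sigmaGN, rep(1, n8), rep(Inf, n8))
    out
  })
  if (sigmaMu == 0 && sigmaGN == 0) media <- m
  media$mu_s_prime <- musPrime(media$mu_s, media$g)
  new("SampledPropertySet", media = media,
      seed = if (is.null(seed)) NA_real_ else seed,
      predictors = reducePredictors(media))
}

#' @rdname samplePropertySet
#' @param object a \code{SampledPropertySet}.
#' @export
predictors <- function(object) object@predictors

#' Reduce a media table to the 24-predictor vector
#'
#' mu_s and g are combined into the reduced scattering coefficient
#' mu_s' = mu_s * (1 - g), so each of the eight media contributes three
#' predictors: mu_a, mu_s' and n. The ordering is fixed and medium-major:
#' \code{<medium>.mu_a}, \code{<medium>.mu_s_prime}, \code{<medium>.n} for
#' the seven skin layers in stack order, then blood.
#'
#' @param media an 8-row optical-property table or a
#'   \code{SampledPropertySet}.
#' @return a named numeric vector of length 24.
#' @examples
#' length(reducePredictors(defaultMediaProperties()))
#' @export
reducePredictors <- function(media) {
  if (is(media, "SampledPropertySet")) media <- media@media
  validateOpticalProperties(media)
  key <- gsub("[^a-z0-9]+", "_", tolower(media$name))
  vals <- as.vector(t(cbind(media$mu_a, musPrime(media$mu_s, media$g),
                            media$n)))
  names(vals) <- as.vector(t(outer(key, c("mu_a", "mu_s_prime", "n"),
                                   paste, sep = ".")))
  vals
}

#' @rdname reducePredictors
#' @export
predictorNames <- function(media = defaultMediaProperties())
  names(reducePredictors(media))

#' Round-trip a media table to CSV
#'
#' One row per medium with columns name, mu_a, mu_s, g, n (mu_s_prime is
#' re-derived on read).
#'
#' @param media optical-property table.
#' @param path CSV file path.
#' @return \code{writePropertySet} returns the path invisibly;
#'   \code{readPropertySet} returns the validated table.
#' @export
writePropertySet <- function(media, path) {
  write.csv(media[c("name", "mu_a", "mu_s", "g", "n")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writePropertySet
#' @export
readPropertySet <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  opticalProperties(m$mu_a, m$mu_s, m$g, m$n, name = m$name)
}
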