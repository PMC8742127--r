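#' Construct a table of optical properties
#'
#' Optical properties of a medium at a fixed wavelength: absorption
#' coefficient \code{mu_a} (mm^-1), scattering coefficient \code{mu_s}
#' (mm^-1), scattering anisotropy \code{g} (mean cosine of the deflection
#' angle, dimensionless) and refractive index \code{n}. The reduced
#' scattering coefficient \code{mu_s_prime = mu_s * (1 - g)} is derived and
#' stored alongside.
#'
#' @param mu_a absorption coefficient(s), mm^-1, >= 0.
#' @param mu_s scattering coefficient(s), mm^-1, >= 0.
#' @param g anisotropy factor(s), in (-1, 1).
#' @param n refractive index(es), >= 1.
#' @param name optional medium name(s).
#' @return a \code{data.frame} with columns \code{name}, \code{mu_a},
#'   \code{mu_s}, \code{g}, \code{n}, \code{mu_s_prime}; one row per medium.
#' @examples
#' opticalProperties(mu_a = 0.5, mu_s = 30, g = 0.9, n = 1.4)
#' @export
opticalProperties <- function(mu_a, mu_s, g, n,
                              name = paste0("medium", seq_along(mu_a))) {
  props <- data.frame(name = as.character(name), mu_a = as.numeric(mu_a),
                      mu_s = as.numeric(mu_s), g = as.numeric(g),
                      n = as.numeric(n), stringsAsFactors = FALSE)
  props$mu_s_prime <- musPrime(props$mu_s, props$g)
  validateOpticalProperties(props)
  props
}

#' Reduced scattering coefficient
#'
#' @param mu_s scattering coefficient (mm^-1).
#' @param g anisotropy factor.
#' @return \code{mu_s * (1 - g)}.
#' @export
musPrime <- function(mu_s, g) mu_s * (1 - g)

validateOpticalProperties <- function(props) {
  required <- c("mu_a", "mu_s", "g", "n")
  missing <- setdiff(required, names(props))
  if (length(missing) > 0L)
    stop("optical-property table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(as.matrix(props[required]))))
    stop("optical properties must be finite")
  if (any(props$mu_a < 0)) stop("mu_a must be >= 0")
  if (any(props$mu_s < 0)) stop("mu_s must be >= 0")
  if (any(props$g <= -1 | props$g >= 1)) stop("g must lie in (-1, 1)")
  if (any(props$n < 1)) stop("n must be >= 1")
  if (!is.null(props$mu_s_prime) &&
      any(abs(props$mu_s_prime - musPrime(props$mu_s, props$g)) >
          1e-9 * pmax(1, props$mu_s)))
    stop("mu_s_prime inconsistent with mu_s * (1 - g)")
  invisible(TRUE)
}

#' Default seven-layer skin stack
#'
#' Layer names and thicknesses of the simulated skin. Thicknesses are
#' configurable placeholders in the style of published multi-layer skin
#' models; the bottom subcutaneous layer is trimmed to the volume depth when
#' the volume is built.
#'
#' @return a \code{data.frame} with columns \code{name} and
#'   \code{thickness_um}.
#' @export
defaultSkinLayers <- function() {
  data.frame(
    name = c("stratum corneum", "epidermis", "papillary dermis",
             "upper blood net dermis", "reticular dermis",
             "deep blood net dermis", "subcutaneous tissue"),
    thickness_um = c(20, 80, 150, 80, 1500, 100, 6000),
    stringsAsFactors = FALSE)
}

#' Default optical properties of the eight media at 424 nm
#'
#' Base optical properties of the seven skin layers plus blood
#' (oxyhaemoglobin at 15 g/dl) at the 424 nm illumination wavelength. These
#' are literature-style placeholder values -- configurable, never hard-coded
#' into any algorithm -- because no authoritative per-layer table ships with
#' the package. Blood absorbs very strongly at 424 nm (Soret band), which is
#' what makes capillaries visible in the SP-DRI signal.
#'
#' @return a \code{data.frame} of eight \code{\link{opticalProperties}} rows;
#'   the first seven rows match \code{\link{defaultSkinLayers}} order, the
#'   eighth row is blood.
#' @export
defaultMediaProperties <- function() {
  # short-wavelength (424 nm) skin optics: scattering and absorption are
  # considerably stronger than in the red/NIR window; the reduced
  # scattering of the two outermost layers sits in the range over which the
  # reference beta0/beta1 calibration surfaces vary
  layers <- defaultSkinLayers()$name
  opticalProperties(
    name = c(layers, "blood"),
    mu_a = c(1.50, 2.50, 1.20, 1.80, 1.00, 1.50, 0.60, 300),
    mu_s = c(60,   45,   55,   60,   50,   55,   35,   150),
    g    = c(0.94, 0.88, 0.90, 0.92, 0.87, 0.93, 0.80, 0.99),
    n    = c(1.50, 1.34, 1.40, 1.39, 1.40, 1.38, 1.44, 1.40))
}
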