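#' Study configuration files
#'
#' A study configuration bundles the geometry, the layer stack, the base
#' optical properties and the engine settings as a plain list that
#' round-trips to YAML. Two presets ship with the package under
#' \code{inst/extdata}: \code{preset_paper.yaml} (full-scale volume, 1e10
#' photons) and \code{preset_desk.yaml} (240 x 240 x 500 voxels, 1e6
#' photons).
#'
#' @param preset "paper" or "desk".
#' @return a study-configuration list with elements \code{geometry}
#'   (a \code{SkinGeometry}), \code{layers}, \code{media}, \code{source},
#'   \code{detector} and \code{mc}.
#' @examples
#' cfg <- studyConfig("desk")
#' cfg$mc$nPhotons
#' @export
studyConfig <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  geometry <- if (preset == "desk") deskGeometry() else skinGeometry()
  list(preset = preset,
       geometry = geometry,
       layers = defaultSkinLayers(),
       media = defaultMediaProperties(),
       source = list(coreDiameter = 20, na = 0.35),
       detector = list(na = if (preset == "desk") 1 else 0.25,
                       pixelBin = 1L),
       mc = list(nPhotons = if (preset == "desk") 1e6 else 1e10,
                 rouletteThreshold = 0.01, rouletteFactor = 10,
                 nExternal = 1.0))
}

geometryToList <- function(g) {
  list(dims = as.integer(g@dims), voxelSize = g@voxelSize,
       loops = as.list(g@loops), plexusX = g@plexusX, plexusY = g@plexusY,
       loopZ = g@loopZ, plexusZ = g@plexusZ, capDiameter = g@capDiameter,
       svpDiameter = g@svpDiameter,
       sourcePositions = lapply(1:2, function(i) g@sourcePositions[i, ]),
       crossSectionX = g@crossSectionX)
}

geometryFromList <- function(l) {
  skinGeometry(capDiameter = l$capDiameter, svpDiameter = l$svpDiameter,
               dims = unlist(l$dims), voxelSize = l$voxelSize,
               loops = as.data.frame(l$loops),
               plexusX = unlist(l$plexusX), plexusY = unlist(l$plexusY),
               loopZ = unlist(l$loopZ), plexusZ = l$plexusZ,
               sourcePositions = do.call(rbind, lapply(l$sourcePositions,
                                                       unlist)),
               crossSectionX = l$crossSectionX)
}

#' @rdname studyConfig
#' @param config a study-configuration list.
#' @param path YAML file path.
#' @export
writeStudyConfig <- function(config, path) {
  out <- config
  out$geometry <- geometryToList(config$geometry)
  out$layers <- as.list(config$layers)
  out$media <- as.list(config$media[c("name", "mu_a", "mu_s", "g", "n")])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname studyConfig
#' @export
readStudyConfig <- function(path) {
  l <- yaml::read_yaml(path)
  l$geometry <- geometryFromList(l$geometry)
  l$layers <- as.data.frame(l$layers)
  m <- as.data.frame(l$media)
  l$media <- opticalProperties(m$mu_a, m$mu_s, m$g, m$n, name = m$name)
  l$detector$pixelBin <- as.integer(l$detector$pixelBin)
  l
}
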