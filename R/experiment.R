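#' @rdname ExperimentPlan
#' @export
setClass("ExperimentPlan", representation(
  nPropertySets = "integer",
  diameters = "numeric",
  sourcePositions = "matrix",
  idealRun = "logical",
  scalePreset = "character",
  commonRandomNumbers = "logical",
  masterSeed = "numeric"))

setValidity("ExperimentPlan", function(object) {
  msg <- character()
  if (object@nPropertySets < 1) msg <- c(msg, "nPropertySets must be >= 1")
  if (nrow(object@sourcePositions) != 2L)
    msg <- c(msg, "exactly two source positions required")
  if (!object@scalePreset %in% c("paper", "desk"))
    msg <- c(msg, "scalePreset must be 'paper' or 'desk'")
  if (length(msg)) msg else TRUE
})

#' Study plan
#'
#' Describes the full simulation study: how many optical-property sets to
#' draw, which capillary diameters to simulate, and the two source
#' positions per diameter. The default plan is the full-scale design: 236
#' property sets x 6 diameters x 2 source positions = 2832 runs. The desk
#' preset replaces the volume with \code{\link{deskGeometry}} and the photon
#' budget with 1e6 packets.
#'
#' @param nPropertySets number of perturbed optical-property sets.
#' @param diameters capillary diameters, um.
#' @param sourcePositions 2 x 2 matrix of source (x, y), px.
#' @param idealRun also simulate the unperturbed base properties (used for
#'   the fixed-value calibration baseline).
#' @param scalePreset "paper" (950 x 950 x 2000 voxels, 1e10 photons) or
#'   "desk" (240 x 240 x 500 voxels, 1e6 photons).
#' @param commonRandomNumbers reuse one seed per (property set, source
#'   position) across the diameter series instead of drawing an independent
#'   seed per run. Adjacent-diameter K_norm differences are then paired
#'   comparisons whose shared photon noise cancels -- the standard
#'   variance-reduction design when the photon budget is small. Default:
#'   on for the desk preset, off (independent seeds, the full-scale study
#'   contract) otherwise.
#' @param masterSeed master seed from which all per-run seeds derive.
#' @return an \code{ExperimentPlan}.
#' @aliases ExperimentPlan-class
#' @rdname ExperimentPlan
#' @examples
#' nrow(enumerateRuns(experimentPlan()))   # 2832
#' @export
experimentPlan <- function(nPropertySets = 236, diameters = seq(4, 14, 2),
                           sourcePositions = rbind(c(250, 250),
                                                   c(250, 360)),
                           idealRun = FALSE, scalePreset = "paper",
                           commonRandomNumbers = scalePreset == "desk",
                           masterSeed = 1) {
  new("ExperimentPlan", nPropertySets = as.integer(nPropertySets),
      diameters = diameters, sourcePositions = sourcePositions,
      idealRun = idealRun, scalePreset = scalePreset,
      commonRandomNumbers = commonRandomNumbers, masterSeed = masterSeed)
}

setMethod("show", "ExperimentPlan", function(object) {
  cat(sprintf("ExperimentPlan (%s): %d property sets x %d diameters x 2 positions = %d runs%s\n",
              object@scalePreset, object@nPropertySets,
              length(object@diameters),
              object@nPropertySets * length(object@diameters) * 2L,
              if (object@idealRun) " (+ ideal run)" else ""))
})

#' Derive a per-run seed
#'
#' Counter-based seed derivation: two rounds of a Lehmer-style multiplier
#' mix the master seed with the run index, then the result is mapped into
#' (0, 2^31) with both limits excluded. Exact in double arithmetic (all
#' intermediates stay below 2^53), hence stable across platforms.
#'
#' @param masterSeed master seed.
#' @param index run index (>= 1).
#' @return integer-valued seed in [1, 2^31 - 2].
#' @export
runSeed <- function(masterSeed, index) {
  m <- 2147483647
  s <- (abs(masterSeed) %% m)
  s <- (s * 48271 + index) %% m
  s <- (s * 48271 + 12345) %% m
  s %% (2^31 - 2) + 1
}

#' Enumerate the study runs
#'
#' Deterministic, stable ordering: property set (slowest), then diameter,
#' then source position. When the plan requests an ideal run, unperturbed
#' runs (property set 0) for every diameter and position are appended.
#'
#' @param plan an \code{\link{experimentPlan}}.
#' @return a data.frame with columns \code{run}, \code{propertySet},
#'   \code{diameter}, \code{position}, \code{sourceX}, \code{sourceY},
#'   \code{seed}.
#' @export
enumerateRuns <- function(plan) {
  stopifnot(is(plan, "ExperimentPlan"))
  sets <- seq_len(plan@nPropertySets)
  if (plan@idealRun) sets <- c(sets, 0L)
  grid <- expand.grid(position = 1:2, diameter = plan@diameters,
                      propertySet = sets)[, 3:1]
  grid$run <- seq_len(nrow(grid))
  grid$sourceX <- plan@sourcePositions[grid$position, 1]
  grid$sourceY <- plan@sourcePositions[grid$position, 2]
  grid$seed <- if (plan@commonRandomNumbers)
    runSeed(plan@masterSeed, grid$propertySet * 1009 + grid$position)
  else runSeed(plan@masterSeed, grid$run)
  grid[c("run", "propertySet", "diameter", "position", "sourceX",
         "sourceY", "seed")]
}

# FNV-1a hash of a character scalar, as hex (manifest config fingerprint);
# 32-bit arithmetic carried exactly in doubles via 16-bit limb splitting
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 2^32
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

pipelineHash <- function(config)
  fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))

scaledSpdriParams <- function(geometry) {
  ny <- geometry@dims[2]
  frame <- round(151 * ny / 950)
  if (frame %% 2 == 0) frame <- frame + 1
  frame <- max(frame, 7)
  list(sigma = 10 * ny / 950, frame = frame,
       shift = round(geometry@sourcePositions[2, ] -
                       geometry@sourcePositions[1, ]))
}

#' Capillary loop centers
#'
#' The y-center of each loop (midpoint of its two limbs), sorted; these are
#' the capillary positions handed to \code{\link{computeKnorm}}.
#'
#' @param geometry a \code{\link{skinGeometry}}.
#' @return sorted numeric vector, px.
#' @export
loopCenters <- function(geometry)
  sort((geometry@loops$y1 + geometry@loops$y2) / 2)

#' Run the simulation study pipeline
#'
#' Drives simulate -> process -> calibrate -> evaluate over an experiment
#' plan with per-run manifests (seed + configuration fingerprint). With
#' \code{resume = TRUE}, runs whose manifest matches the current
#' configuration are skipped; a manifest written under a different
#' configuration aborts the pipeline unless \code{force = TRUE}.
#'
#' Stages: \emph{simulate} renders one reflectance image per (property set,
#' diameter, source position); \emph{process} computes SP-DRI ratio images,
#' filtered cross-section profiles and per-loop K_norm values (smoothing
#' sigma and filter frame scale with the lateral volume size, ratios 10/950
#' and 151/950); \emph{calibrate} reduces one loop's K_norm-vs-diameter
#' series per property set to (beta0, beta1); \emph{evaluate} runs
#' \code{\link{runEvaluation}} when at least 10 property sets are available.
#'
#' @param plan an \code{\link{experimentPlan}}.
#' @param outDir output directory (created).
#' @param geometry volume geometry; defaults to \code{\link{deskGeometry}}
#'   for the desk preset, \code{\link{skinGeometry}} otherwise.
#' @param layers,base layer stack and base optical properties.
#' @param nPhotons photon packets per run (desk default 1e6).
#' @param detector a \code{\link{detectorSpec}}; by default the desk preset
#'   integrates over all exit angles (NA = nExternal) to preserve photon
#'   statistics, while the paper preset applies the 0.25 fiber-bundle NA.
#' @param stages subset of simulate/process/calibrate/evaluate.
#' @param loop 1-based index of the loop used for calibration (default: the
#'   middle loop when three are present, else the last).
#' @param spdriMethod ratio formation passed to \code{\link{computeSPDRI}};
#'   the default \code{"presmooth"} is the photon-starved desk-scale
#'   variant.
#' @param resume skip runs with matching manifests.
#' @param force overwrite stale manifests instead of aborting.
#' @param nExternal external refractive index.
#' @param ... passed to \code{\link{runEvaluation}}.
#' @return a list with elements \code{knorm}, \code{betas}, \code{dataset},
#'   \code{evaluation} (those produced by the requested stages) and
#'   \code{outDir}.
#' @export
runPipeline <- function(plan, outDir, geometry = NULL,
                        layers = defaultSkinLayers(),
                        base = basePropertySet(), nPhotons = 1e6,
                        detector = NULL,
                        stages = c("simulate", "process", "calibrate",
                                   "evaluate"),
                        loop = NULL, spdriMethod = "presmooth",
                        resume = TRUE, force = FALSE,
                        nExternal = 1.0, ...) {
  stopifnot(is(plan, "ExperimentPlan"))
  if (is.null(geometry))
    geometry <- if (plan@scalePreset == "desk") deskGeometry()
                else skinGeometry()
  if (is.null(detector))
    detector <- if (plan@scalePreset == "desk")
                  detectorSpec(na = nExternal) else detectorSpec()
  dir.create(file.path(outDir, "sim"), recursive = TRUE,
             showWarnings = FALSE)
  runs <- enumerateRuns(plan)
  cfg <- list(geometry = geometryToList(geometry),
              media = as.list(base@media[c("mu_a", "mu_s", "g", "n")]),
              layers = layers$thickness_um,
              nPhotons = nPhotons, masterSeed = plan@masterSeed,
              diameters = plan@diameters,
              nPropertySets = plan@nPropertySets,
              detectorNA = detector@na, nExternal = nExternal)
  hash <- pipelineHash(cfg)
  out <- list(outDir = outDir)
  sets <- unique(runs$propertySet)

  sampled <- lapply(setNames(sets, sets), function(s) {
    if (s == 0) base@media
    else samplePropertySet(base, seed = runSeed(plan@masterSeed,
                                                1e6 + s))@media
  })
  propCSV <- file.path(outDir, "property_sets.csv")
  propTable <- do.call(rbind, lapply(sets, function(s)
    cbind(set_id = s, sampled[[as.character(s)]])))
  write.csv(propTable, propCSV, row.names = FALSE)

  simFile <- function(s, d, p)
    file.path(outDir, "sim", sprintf("run_s%03d_d%02g_p%d", s, d, p))

  if ("simulate" %in% stages) {
    for (d in plan@diameters) {
      labels <- NULL
      for (s in sets) {
        vol <- buildTissueVolume(initialize(geometry, capDiameter = d),
                                 layers = layers,
                                 media = sampled[[as.character(s)]])
        for (p in 1:2) {
          stem <- simFile(s, d, p)
          manifest <- paste0(stem, ".json")
          target <- paste0(stem, ".rds")
          if (file.exists(manifest)) {
            old <- jsonlite::read_json(manifest)
            if (old$hash == hash && file.exists(target) && resume) next
            if (old$hash != hash && !force)
              stop("stale manifest for ", basename(stem),
                   "; rerun with force = TRUE")
          }
          if (is.null(labels)) labels <- voxelLabels(vol)
          run <- runs[runs$propertySet == s & runs$diameter == d &
                        runs$position == p, ]
          # the (possibly rescaled) geometry carries the authoritative
          # source coordinates; the plan's positions describe the design
          src <- sourceSpec(x = geometry@sourcePositions[p, 1],
                            y = geometry@sourcePositions[p, 2])
          det <- simulatePhotons(vol, src, detector,
                                 mcConfig(nPhotons = nPhotons,
                                          nExternal = nExternal,
                                          seed = run$seed),
                                 labels = labels)
          img <- renderReflectance(det)
          saveRDS(imageGrid(img), target)
          jsonlite::write_json(list(run = run$run, seed = run$seed,
                                    hash = hash, file = basename(target)),
                               manifest, auto_unbox = TRUE)
        }
      }
      labels <- NULL
    }
  }

  sp <- scaledSpdriParams(geometry)
  centers <- loopCenters(geometry)
  if (is.null(loop)) loop <- if (length(centers) >= 3) 2L
                             else length(centers)

  if ("process" %in% stages) {
    rows <- list()
    for (s in sets) for (d in plan@diameters) {
      fa <- paste0(simFile(s, d, 1), ".rds")
      fb <- paste0(simFile(s, d, 2), ".rds")
      if (!file.exists(fa) || !file.exists(fb)) next
      imgA <- new("ReflectanceImage", grid = readRDS(fa),
                  pixelSize = geometry@voxelSize, photonsLaunched = nPhotons,
                  muaUsed = numeric(), sourceXY = geometry@sourcePositions[1, ])
      imgB <- new("ReflectanceImage", grid = readRDS(fb),
                  pixelSize = geometry@voxelSize, photonsLaunched = nPhotons,
                  muaUsed = numeric(), sourceXY = geometry@sourcePositions[2, ])
      spd <- computeSPDRI(imgA, imgB, shift = sp$shift, sigma = sp$sigma,
                          method = spdriMethod)
      prof <- extractProfile(spd, x = round(geometry@crossSectionX),
                             frame = sp$frame)
      knr <- computeKnorm(prof, centers)
      knr$set_id <- s
      knr$diameter <- d
      rows[[length(rows) + 1L]] <- knr
    }
    out$knorm <- do.call(rbind, rows)
    write.csv(out$knorm, file.path(outDir, "knorm.csv"), row.names = FALSE)
  }

  if ("calibrate" %in% stages && !is.null(out$knorm)) {
    kn <- out$knorm[out$knorm$capillary == loop, ]
    betas <- lapply(split(kn, kn$set_id), function(g) {
      fit <- tryCatch(fitKnormRegression(g$diameter, g$knorm),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      data.frame(set_id = g$set_id[1], beta0 = beta0(fit),
                 beta1 = beta1(fit), r_squared = fit@rSquared,
                 n_missing = fit@nMissing)
    })
    out$betas <- do.call(rbind, betas)
    if (!is.null(out$betas))
      write.csv(out$betas, file.path(outDir, "betas.csv"),
                row.names = FALSE)
  }

  if ("evaluate" %in% stages && !is.null(out$knorm)) {
    kn <- out$knorm[out$knorm$capillary == loop & !out$knorm$missing, ]
    wide <- stats::reshape(kn[c("set_id", "diameter", "knorm")],
                           idvar = "set_id", timevar = "diameter",
                           direction = "wide")
    names(wide) <- sub("^knorm\\.", "knorm_", names(wide))
    preds <- t(vapply(sets[sets > 0], function(s)
      reducePredictors(sampled[[as.character(s)]]), numeric(24)))
    predDf <- data.frame(set_id = sets[sets > 0], preds,
                         check.names = FALSE)
    dataset <- merge(predDf, wide, by = "set_id")
    attr(dataset, "diameters") <- plan@diameters
    out$dataset <- dataset
    if (nrow(dataset) >= 10) {
      fixed <- if (plan@idealRun && !is.null(out$betas) &&
                   any(out$betas$set_id == 0)) {
        b <- out$betas[out$betas$set_id == 0, ]
        c(beta0 = b$beta0, beta1 = b$beta1)
      } else idealBetas(base)
      out$evaluation <- runEvaluation(dataset, fixedBetas = fixed,
                                      seed = runSeed(plan@masterSeed, 999),
                                      ...)
      write.csv(out$evaluation$summary,
                file.path(outDir, "summary.csv"), row.names = FALSE)
    } else {
      message("fewer than 10 property sets; evaluation stage skipped")
    }
  }
  out
}
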