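#' Invert the linear calibration to a capillary diameter
#'
#' Applies the calibration identity
#' \code{diameter = (K_norm - beta0) / beta1} (um).
#'
#' @param knorm K_norm value(s).
#' @param beta0 calibration intercept(s).
#' @param beta1 calibration slope(s); must exceed \code{tol} in magnitude.
#' @param tol degenerate-slope tolerance.
#' @return predicted diameter(s), um.
#' @examples
#' predictDiameter(2 + 0.5 * 8, beta0 = 2, beta1 = 0.5)
#' @export
predictDiameter <- function(knorm, beta0, beta1, tol = 1e-9) {
  if (any(abs(beta1) <= tol))
    stop("degenerate calibration slope |beta1| <= ", tol)
  (knorm - beta0) / beta1
}

# per-row OLS betas of a calibration dataset (responses of the RF stage)
datasetBetas <- function(dataset) {
  d <- attr(dataset, "diameters")
  kn <- as.matrix(dataset[paste0("knorm_", d)])
  t(vapply(seq_len(nrow(kn)), function(i) {
    fit <- fitKnormRegression(d, kn[i, ])
    c(beta0 = beta0(fit), beta1 = beta1(fit))
  }, numeric(2)))
}

#' Calibration parameters of the ideal (unperturbed) run
#'
#' beta0 and beta1 evaluated from the calibration surfaces at the
#' unperturbed base optical properties -- the fixed-value baseline a
#' calibration-free measurement would otherwise have to assume.
#'
#' @param base a \code{\link{basePropertySet}}.
#' @param surfaceB0,surfaceB1 \code{AnalyticCalib} surfaces (defaults: the
#'   published reference surfaces).
#' @return named vector \code{c(beta0, beta1)}.
#' @export
idealBetas <- function(base = basePropertySet(), surfaceB0 = beta0Surface(),
                       surfaceB1 = beta1Surface()) {
  p <- reducePredictors(base@media)
  x1 <- p[["stratum_corneum.mu_s_prime"]]
  x2 <- p[["epidermis.mu_s_prime"]]
  c(beta0 = evalCalibSurface(surfaceB0, x1, x2),
    beta1 = evalCalibSurface(surfaceB1, x1, x2))
}

#' Evaluate calibration-free diameter prediction
#'
#' Repeated hold-out evaluation of absolute diameter prediction: in each of
#' \code{nRepeats} rounds the property sets are split into training (80%)
#' and test (20%) rows; ensemble models for beta0 and beta1 are trained on
#' the training rows' reduced-scattering predictors; each test row's K_norm
#' values are converted to diameters through the inverted linear calibration
#' using betas predicted by (a) the ensemble directly (\code{"rf"}), (b) an
#' analytic two-exponential surface fitted to the probed ensemble response
#' (\code{"analytic"}), or (c) fixed ideal-run values (\code{"fixed"}).
#' Hyperparameters are selected once on the full data (as in the study
#' design), not per repeat.
#'
#' @param dataset a \code{\link{generateCalibrationDataset}}-format
#'   data.frame (diameter grid in \code{attr(, "diameters")}).
#' @param selected predictor column names used by the models (default: the
#'   reduced scattering of the two outermost skin layers).
#' @param nRepeats number of random splits (study value 30).
#' @param testFraction held-out fraction (study value 0.2).
#' @param methods subset of \code{c("rf", "analytic", "fixed")}.
#' @param fixedBetas named \code{c(beta0, beta1)} for the fixed method
#'   (default \code{\link{idealBetas}()}).
#' @param analyticSurfaces optional list with elements \code{beta0} and
#'   \code{beta1} (\code{AnalyticCalib}); when supplied the analytic method
#'   evaluates these surfaces directly instead of fitting to the probed
#'   ensemble (useful for exactness checks).
#' @param hyperparams optional list with elements \code{beta0} and
#'   \code{beta1}, each \code{list(method, learnRate, minLeaf)}; when
#'   missing they are tuned once with \code{\link{tuneAndTrain}}.
#' @param nCycles ensemble learning cycles (study value 500).
#' @param probeN probe-grid resolution per axis (study value 200).
#' @param pool pool predictions across repeats before summarizing instead
#'   of averaging per-repeat summaries.
#' @param seed RNG seed.
#' @return a list with \code{records} (one row per prediction),
#'   \code{summary} (see \code{\link{summarizeRecords}}), \code{nInvalid}
#'   (predictions dropped for non-positive predicted beta1) and
#'   \code{hyperparams}.
#' @export
runEvaluation <- function(dataset,
                          selected = c("stratum_corneum.mu_s_prime",
                                       "epidermis.mu_s_prime"),
                          nRepeats = 30, testFraction = 0.2,
                          methods = c("rf", "analytic", "fixed"),
                          fixedBetas = idealBetas(),
                          analyticSurfaces = NULL, hyperparams = NULL,
                          nCycles = 500, probeN = 200, pool = FALSE,
                          seed = NULL) {
  stopifnot(nrow(dataset) >= 10)
  methods <- match.arg(methods, c("rf", "analytic", "fixed"),
                       several.ok = TRUE)
  d <- attr(dataset, "diameters")
  if (is.null(d)) stop("dataset lacks the diameters attribute")
  kn <- as.matrix(dataset[paste0("knorm_", d)])
  x <- dataset[selected]
  betas <- datasetBetas(dataset)
  n <- nrow(dataset)
  nTest <- max(1L, round(testFraction * n))

  needModels <- "rf" %in% methods ||
    ("analytic" %in% methods && is.null(analyticSurfaces))
  if (needModels && is.null(hyperparams)) {
    hyperparams <- withSeed(seed, list(
      beta0 = tunedParams(x, betas[, "beta0"], nCycles = nCycles),
      beta1 = tunedParams(x, betas[, "beta1"], nCycles = nCycles)))
  }

  records <- list()
  nInvalid <- 0L
  withSeed(seed, {
    for (r in seq_len(nRepeats)) {
      test <- sample(n, nTest)
      train <- setdiff(seq_len(n), test)
      predB <- list()
      if (needModels) {
        models <- lapply(c(beta0 = "beta0", beta1 = "beta1"), function(b) {
          hp <- hyperparams[[b]]
          trainEnsembleModel(x[train, , drop = FALSE], betas[train, b],
                             method = hp$method, learnRate = hp$learnRate,
                             minLeaf = hp$minLeaf, nCycles = nCycles)
        })
        if ("rf" %in% methods)
          predB$rf <- cbind(
            beta0 = predictEnsemble(models$beta0, x[test, , drop = FALSE]),
            beta1 = predictEnsemble(models$beta1, x[test, , drop = FALSE]))
      }
      if ("analytic" %in% methods) {
        surfs <- analyticSurfaces
        if (is.null(surfs)) {
          surfs <- lapply(c(beta0 = "beta0", beta1 = "beta1"), function(b) {
            probe <- probeModelSurface(models[[b]], x[train, 1], x[train, 2],
                                       n = probeN)
            fitAnalyticSurface(probe$x1, probe$x2, probe$z, response = b)
          })
        }
        predB$analytic <- cbind(
          beta0 = evalCalibSurface(surfs$beta0, x[test, 1], x[test, 2]),
          beta1 = evalCalibSurface(surfs$beta1, x[test, 1], x[test, 2]))
      }
      if ("fixed" %in% methods)
        predB$fixed <- cbind(beta0 = rep(fixedBetas[["beta0"]], nTest),
                             beta1 = rep(fixedBetas[["beta1"]], nTest))
      for (m in names(predB)) {
        b0 <- predB[[m]][, "beta0"]
        b1 <- predB[[m]][, "beta1"]
        ok <- b1 > 1e-9
        nInvalid <- nInvalid + sum(!ok) * length(d)
        if (!any(ok)) next
        pred <- (kn[test[ok], , drop = FALSE] - b0[ok]) / b1[ok]
        records[[length(records) + 1L]] <- data.frame(
          repeat_id = r, method = m,
          set_id = rep(dataset$set_id[test[ok]], times = length(d)),
          true_diameter = rep(d, each = sum(ok)),
          predicted = as.vector(pred))
      }
    }
  })
  records <- do.call(rbind, records)
  list(records = records, summary = summarizeRecords(records, pool = pool),
       nInvalid = nInvalid, hyperparams = hyperparams)
}

tunedParams <- function(x, y, nCycles) {
  m <- tuneAndTrain(x, y, nCycles = min(nCycles, 200), cvCycles = 100)
  list(method = m@method, learnRate = m@params$learnRate,
       minLeaf = m@params$minLeaf)
}

#' Summarize diameter predictions
#'
#' Mean, median, sample SD and coefficient of variation
#' (CV = 100 * SD / mean) of the predicted diameters per prediction method
#' and true diameter. By default per-repeat summaries are averaged across
#' repeats; with \code{pool = TRUE} all predictions are pooled first. Cells
#' with fewer than two predictions are flagged and excluded. The overall CV
#' per method (mean across diameters) is attached as
#' \code{attr(, "overall")}.
#'
#' @param records prediction records (\code{\link{runEvaluation}} format).
#' @param pool pool across repeats instead of averaging per-repeat
#'   summaries.
#' @return a data.frame with columns \code{method}, \code{true_diameter},
#'   \code{mean}, \code{median}, \code{sd}, \code{cv}, \code{n},
#'   \code{flagged}.
#' @export
summarizeRecords <- function(records, pool = FALSE) {
  cellStats <- function(p) {
    if (length(p) < 2L)
      return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
               cv = NA_real_, n = length(p)))
    m <- mean(p)
    s <- sd(p)
    c(mean = m, median = median(p), sd = s,
      cv = if (m != 0) 100 * s / abs(m) else NA_real_, n = length(p))
  }
  groups <- if (pool) list(records$method, records$true_diameter)
            else list(records$method, records$true_diameter,
                      records$repeat_id)
  parts <- split(records$predicted, groups, drop = FALSE)
  keys <- expand.grid(lapply(groups, function(g) sort(unique(g))),
                      stringsAsFactors = FALSE)
  stats <- t(vapply(parts, cellStats, numeric(5)))
  df <- cbind(keys, as.data.frame(stats))
  names(df)[1:2] <- c("method", "true_diameter")
  if (!pool) {
    agg <- lapply(split(df, list(df$method, df$true_diameter)), function(g) {
      ok <- !is.na(g$mean)
      data.frame(method = g$method[1], true_diameter = g$true_diameter[1],
                 mean = mean(g$mean[ok]), median = mean(g$median[ok]),
                 sd = mean(g$sd[ok]), cv = mean(g$cv[ok]),
                 n = sum(g$n), flagged = !any(ok))
    })
    df <- do.call(rbind, agg)
  } else {
    df$flagged <- is.na(df$mean)
  }
  rownames(df) <- NULL
  df <- df[order(df$method, df$true_diameter), ]
  overall <- vapply(split(df, df$method),
                    function(g) mean(g$cv, na.rm = TRUE), numeric(1))
  attr(df, "overall") <- data.frame(method = names(overall),
                                    cv = unname(overall))
  df
}
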