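# run an expression under a temporary, restorable RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @rdname LinearFit
#' @export
setClass("LinearFit", representation(
  beta0 = "numeric", beta1 = "numeric", rSquared = "numeric",
  nUsed = "integer", nMissing = "integer"))

setMethod("show", "LinearFit", function(object) {
  cat(sprintf("LinearFit: beta0 = %.4f, beta1 = %.4f (R^2 = %.4f, n = %d, %d missing)\n",
              object@beta0, object@beta1, object@rSquared, object@nUsed,
              object@nMissing))
})

#' Linear calibration of K_norm against capillary diameter
#'
#' Ordinary least squares of K_norm on the capillary diameter. Because
#' K_norm grows linearly with the diameter, each simulated individual (one
#' set of optical properties) is reduced to an intercept \code{beta0} and a
#' slope \code{beta1}; inverting the line converts a measured K_norm back
#' into an absolute diameter (see \code{\link{predictDiameter}}). Missing
#' K_norm entries (capillaries whose extrema were not found) are skipped and
#' counted.
#'
#' @param diameters capillary diameters (um).
#' @param knorm matching K_norm values; may contain \code{NA}.
#' @return a \code{LinearFit} object with accessors \code{beta0()},
#'   \code{beta1()}.
#' @aliases LinearFit-class
#' @rdname LinearFit
#' @examples
#' fit <- fitKnormRegression(seq(4, 14, 2), 2 + 0.5 * seq(4, 14, 2))
#' beta1(fit)
#' @export
fitKnormRegression <- function(diameters, knorm) {
  stopifnot(length(diameters) == length(knorm))
  ok <- is.finite(knorm) & is.finite(diameters)
  if (sum(ok) < 2L)
    stop("need at least two non-missing (diameter, K_norm) pairs")
  fit <- lm(knorm[ok] ~ diameters[ok])
  ss <- sum((knorm[ok] - mean(knorm[ok]))^2)
  r2 <- if (ss > 0) 1 - sum(resid(fit)^2) / ss else 1
  new("LinearFit", beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
      rSquared = max(0, min(1, r2)), nUsed = sum(ok),
      nMissing = sum(!ok))
}

#' @rdname LinearFit
#' @param object a \code{LinearFit}.
#' @export
beta0 <- function(object) object@beta0

#' @rdname LinearFit
#' @export
beta1 <- function(object) object@beta1

#' @rdname AnalyticCalib
#' @export
setClass("AnalyticCalib", representation(
  a1 = "numeric", b1 = "numeric", a2 = "numeric", b2 = "numeric",
  c = "numeric", rSquared = "numeric", response = "character"))

setValidity("AnalyticCalib", function(object) {
  if (object@b1 < 0 || object@b2 < 0)
    "decay rates b1, b2 must be >= 0" else TRUE
})

setMethod("show", "AnalyticCalib", function(object) {
  cat(sprintf(
    "AnalyticCalib (%s): z = %.4g*exp(-%.4g*x1) + %.4g*exp(-%.4g*x2) + %.4g  (R^2 = %.4f)\n",
    object@response, object@a1, object@b1, object@a2, object@b2, object@c,
    object@rSquared))
})

#' Analytic two-exponential calibration surfaces
#'
#' The dependence of the calibration parameters beta1 (slope) and beta0
#' (intercept) on the reduced scattering coefficients of the two outermost
#' skin layers is described by a sum of two decaying exponentials plus a
#' constant:
#' \deqn{z = a_1 e^{-b_1 x_1} + a_2 e^{-b_2 x_2} + c}
#' where \eqn{x_1, x_2} are mu_s' of the stratum corneum and of the
#' epidermis (mm^-1). \code{analyticCalib} constructs such a surface;
#' \code{beta1Surface()} and \code{beta0Surface()} return the published
#' reference coefficient sets
#' (beta1: 1.251, 0.3319, 1.046, 0.6513, 0.1389;
#' beta0: -3.803, 0.4382, -2.356, 0.6406, -0.4093), which also serve as the
#' surrogate generator's default beta surfaces. \code{evalCalibSurface}
#' evaluates a surface and \code{surfaceAsymptote} returns its limiting
#' value as both predictors grow without bound (the constant term).
#'
#' @param a1,b1,a2,b2,c surface coefficients.
#' @param rSquared fit quality (1 for exact/reference surfaces).
#' @param response which parameter the surface models, "beta0" or "beta1".
#' @return an \code{AnalyticCalib} object.
#' @aliases AnalyticCalib-class
#' @rdname AnalyticCalib
#' @examples
#' s <- beta1Surface()
#' evalCalibSurface(s, x1 = 3.6, x2 = 5.2)
#' surfaceAsymptote(s)
#' @export
analyticCalib <- function(a1, b1, a2, b2, c, rSquared = 1,
                          response = "beta1") {
  new("AnalyticCalib", a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c,
      rSquared = rSquared, response = response)
}

#' @rdname AnalyticCalib
#' @export
beta1Surface <- function()
  analyticCalib(1.251, 0.3319, 1.046, 0.6513, 0.1389, response = "beta1")

#' @rdname AnalyticCalib
#' @export
beta0Surface <- function()
  analyticCalib(-3.803, 0.4382, -2.356, 0.6406, -0.4093, response = "beta0")

# internal aliases usable where argument names shadow the constructors
spdriBeta1Default <- beta1Surface
spdriBeta0Default <- beta0Surface

#' @rdname AnalyticCalib
#' @param surface an \code{AnalyticCalib}.
#' @param x1,x2 reduced scattering of skin layers 1 and 2 (mm^-1).
#' @export
evalCalibSurface <- function(surface, x1, x2) {
  surface@a1 * exp(-surface@b1 * x1) +
    surface@a2 * exp(-surface@b2 * x2) + surface@c
}

#' @rdname AnalyticCalib
#' @export
surfaceAsymptote <- function(surface) surface@c

#' Fit the two-exponential calibration surface
#'
#' Nonlinear least squares of \code{z = a1*exp(-b1*x1) + a2*exp(-b2*x2) + c}
#' with multistart initialization: decay rates start from a small grid
#' (default 0.1, 0.5, 1 per axis) and, for each start, the amplitudes and
#' constant -- which enter linearly -- are initialized by an exact linear
#' solve. The best converged fit by residual sum of squares is returned. No
#' interaction term is used. Near-constant responses short-circuit to the
#' degenerate surface (a1 = a2 = 0, c = mean(z)).
#'
#' @param x1,x2 predictor samples (mu_s' of skin layers 1 and 2, mm^-1).
#' @param z response samples (beta0 or beta1 values).
#' @param response label stored in the result.
#' @param rateStarts decay-rate start values for the multistart grid.
#' @return an \code{AnalyticCalib} with fitted coefficients and R^2.
#' @examples
#' g <- expand.grid(x1 = seq(0.5, 6, length.out = 20),
#'                  x2 = seq(0.5, 6, length.out = 20))
#' z <- evalCalibSurface(beta1Surface(), g$x1, g$x2)
#' fitAnalyticSurface(g$x1, g$x2, z)
#' @export
fitAnalyticSurface <- function(x1, x2, z, response = "beta1",
                               rateStarts = c(0.1, 0.5, 1)) {
  stopifnot(length(x1) == length(x2), length(x1) == length(z))
  if (length(z) < 10L || diff(range(x1)) <= 0 || diff(range(x2)) <= 0)
    stop("need >= 10 points spanning both predictor axes")
  tss <- sum((z - mean(z))^2)
  if (tss < 1e-20 * max(1, length(z))) {
    return(analyticCalib(0, 1, 0, 1, mean(z), rSquared = 1,
                         response = response))
  }
  dat <- data.frame(x1 = x1, x2 = x2, z = z)
  best <- NULL
  bestRss <- Inf
  for (b1s in rateStarts) for (b2s in rateStarts) {
    # amplitudes/constant are linear given the decay rates
    X <- cbind(exp(-b1s * x1), exp(-b2s * x2), 1)
    lin <- tryCatch(qr.solve(X, z), error = function(e) c(0, 0, mean(z)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ a1 * exp(-b1 * x1) + a2 * exp(-b2 * x2) + c,
        data = dat,
        start = list(a1 = lin[1], b1 = b1s, a2 = lin[2], b2 = b2s,
                     c = lin[3]),
        lower = c(a1 = -Inf, b1 = 0, a2 = -Inf, b2 = 0, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (rss < bestRss) {
      bestRss <- rss
      best <- coef(fit)
    }
  }
  if (is.null(best))
    stop("analytic surface fit did not converge from any start; best RSS = ",
         format(bestRss))
  analyticCalib(unname(best["a1"]), unname(best["b1"]), unname(best["a2"]),
                unname(best["b2"]), unname(best["c"]),
                rSquared = max(0, min(1, 1 - bestRss / tss)),
                response = response)
}

#' Rank predictors by out-of-bag permuted importance
#'
#' Trains a bagged regression tree ensemble in which every predictor is
#' available at each split (\code{mtry =} number of predictors) and scores
#' each predictor by the mean increase of the out-of-bag squared error when
#' its values are permuted. This is the standard screen for deciding which
#' optical properties drive beta0 / beta1.
#'
#' @param predictors data.frame or matrix of predictors (one column each).
#' @param response numeric response (beta0 or beta1 per property set).
#' @param nTrees ensemble size.
#' @param seed optional RNG seed.
#' @return a data.frame with columns \code{predictor}, \code{importance},
#'   \code{rank}, ordered by decreasing importance.
#' @examples
#' x <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
#' y <- 3 * x[[2]] + rnorm(200, 0, 0.1)
#' head(rankPredictors(x, y, nTrees = 100, seed = 1))
#' @export
rankPredictors <- function(predictors, response, nTrees = 500, seed = NULL) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) < 30L)
    stop("need at least 30 rows to rank predictors")
  if (anyNA(predictors) || anyNA(response))
    stop("predictors and response must be complete")
  if (var(response) == 0) {
    warning("constant response: all importances are zero")
    scores <- setNames(rep(0, ncol(predictors)), colnames(predictors))
  } else {
    fit <- withSeed(seed, randomForest::randomForest(
      x = predictors, y = response, ntree = nTrees,
      mtry = ncol(predictors), importance = TRUE, keep.forest = FALSE))
    scores <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  }
  ord <- order(scores, decreasing = TRUE)
  data.frame(predictor = names(scores)[ord],
             importance = unname(scores[ord]),
             rank = seq_along(scores), stringsAsFactors = FALSE)
}

#' @rdname EnsembleModel
#' @export
setClass("EnsembleModel", representation(
  method = "character",       # "bagging" or "lsboost"
  params = "list",            # learnRate, minLeaf
  nCycles = "integer",
  model = "ANY",
  predictorNames = "character",
  cvMSE = "numeric",
  trainR2 = "numeric"))

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %s, %d cycles", object@method, object@nCycles))
  if (object@method == "lsboost")
    cat(sprintf(", learning rate %.3g", object@params$learnRate))
  cat(sprintf(", min leaf %d (CV MSE %.4g, train R^2 %.4f)\n",
              object@params$minLeaf, object@cvMSE, object@trainR2))
})

trainEnsemble <- function(x, y, method, learnRate, minLeaf, nCycles, seed) {
  x <- as.matrix(x)
  if (method == "bagging") {
    withSeed(seed, randomForest::randomForest(
      x = x, y = y, ntree = nCycles, mtry = ncol(x), nodesize = minLeaf))
  } else {
    withSeed(seed, xgboost::xgboost(
      x = x, y = y, nrounds = nCycles, learning_rate = learnRate,
      min_child_weight = minLeaf, max_depth = 6L, nthreads = 1L,
      verbosity = 0L, seed = if (is.null(seed)) 0L else seed))
  }
}

predictEnsembleRaw <- function(model, newdata) {
  as.numeric(predict(model, as.matrix(newdata)))
}

#' Cross-validated hyperparameter search and ensemble training
#'
#' Searches a small grid over the ensemble aggregation method (bagging of
#' regression trees, or least-squares gradient boosting), the boosting
#' learning rate and the minimum observations per leaf by 5-fold
#' cross-validated mean squared error, then retrains the selected
#' configuration on all data with a fixed, large number of learning cycles
#' (default 500) for prediction stability.
#'
#' @param predictors data.frame or matrix of selected predictors.
#' @param response numeric response.
#' @param nCycles learning cycles of the final model.
#' @param cvCycles learning cycles used during the CV search.
#' @param nFolds number of CV folds.
#' @param learnRates boosting learning-rate grid.
#' @param minLeaf minimum-leaf-size grid.
#' @param methods aggregation methods to search.
#' @param seed optional RNG seed (controls folds and tree randomness).
#' @return an \code{EnsembleModel}; use \code{predictEnsemble} on new data.
#' @examples
#' x <- data.frame(x1 = runif(80, 0.5, 6), x2 = runif(80, 0.5, 6))
#' y <- evalCalibSurface(beta1Surface(), x$x1, x$x2)
#' m <- tuneAndTrain(x, y, nCycles = 100, cvCycles = 50, seed = 1)
#' cor(predictEnsemble(m, x), y)
#' @export
tuneAndTrain <- function(predictors, response, nCycles = 500,
                         cvCycles = 150, nFolds = 5,
                         learnRates = c(0.05, 0.1, 0.35, 0.5),
                         minLeaf = c(1, 3, 5),
                         methods = c("bagging", "lsboost"), seed = NULL) {
  x <- as.data.frame(predictors)
  y <- as.numeric(response)
  n <- length(y)
  if (n < 30L) stop("need at least 30 rows to tune an ensemble")
  grid <- rbind(
    if ("bagging" %in% methods)
      expand.grid(method = "bagging", learnRate = NA_real_,
                  minLeaf = minLeaf, stringsAsFactors = FALSE),
    if ("lsboost" %in% methods)
      expand.grid(method = "lsboost", learnRate = learnRates,
                  minLeaf = minLeaf, stringsAsFactors = FALSE))
  folds <- withSeed(seed, sample(rep_len(seq_len(nFolds), n)))
  if (min(table(folds)) < 2L) stop("degenerate cross-validation folds")
  cvmse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(nFolds), function(k) {
      tr <- folds != k
      fit <- trainEnsemble(x[tr, , drop = FALSE], y[tr],
                           grid$method[i], grid$learnRate[i],
                           grid$minLeaf[i], cvCycles,
                           seed = if (is.null(seed)) NULL else seed + k)
      mean((predictEnsembleRaw(fit, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cvmse)
  final <- trainEnsemble(x, y, grid$method[best], grid$learnRate[best],
                         grid$minLeaf[best], nCycles, seed = seed)
  pred <- predictEnsembleRaw(final, x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - pred)^2) / tss else 0
  new("EnsembleModel", method = grid$method[best],
      params = list(learnRate = grid$learnRate[best],
                    minLeaf = as.integer(grid$minLeaf[best])),
      nCycles = as.integer(nCycles), model = final,
      predictorNames = colnames(x), cvMSE = cvmse[best],
      trainR2 = max(0, min(1, r2)))
}

#' Ensemble regression with fixed hyperparameters
#'
#' Trains a bagging or least-squares boosting ensemble at a given
#' configuration, skipping the cross-validated search (used when the
#' hyperparameters were already selected once for the study).
#'
#' @inheritParams tuneAndTrain
#' @param method "bagging" or "lsboost".
#' @param learnRate boosting shrinkage (ignored for bagging).
#' @param minLeaf minimum observations per leaf.
#' @return an \code{EnsembleModel}.
#' @aliases EnsembleModel-class
#' @rdname EnsembleModel
#' @export
trainEnsembleModel <- function(predictors, response, method = "bagging",
                               learnRate = 0.35, minLeaf = 1,
                               nCycles = 500, seed = NULL) {
  x <- as.data.frame(predictors)
  y <- as.numeric(response)
  final <- trainEnsemble(x, y, method, learnRate, minLeaf, nCycles, seed)
  pred <- predictEnsembleRaw(final, x)
  tss <- sum((y - mean(y))^2)
  new("EnsembleModel", method = method,
      params = list(learnRate = learnRate, minLeaf = as.integer(minLeaf)),
      nCycles = as.integer(nCycles), model = final,
      predictorNames = colnames(x),
      cvMSE = NA_real_,
      trainR2 = if (tss > 0) max(0, min(1, 1 - sum((y - pred)^2) / tss))
                else 0)
}

#' @rdname EnsembleModel
#' @param object an \code{EnsembleModel}.
#' @param newdata data.frame/matrix with the model's predictor columns.
#' @export
predictEnsemble <- function(object, newdata) {
  newdata <- as.data.frame(newdata)[, object@predictorNames, drop = FALSE]
  predictEnsembleRaw(object@model, newdata)
}

#' Probe a trained model on a central predictor grid
#'
#' Queries the model response on equidistant values inside the central band
#' (default 20--80%) of each predictor's observed min--max range. The band
#' excludes outliers at the range edges; the probed responses are the data
#' to which \code{\link{fitAnalyticSurface}} is applied.
#'
#' @param model an \code{EnsembleModel}.
#' @param x1,x2 observed predictor samples defining the ranges.
#' @param n equidistant values per predictor.
#' @param band fraction interval of the min--max range to cover.
#' @return a data.frame with columns \code{x1}, \code{x2}, \code{z}
#'   (\code{n * n} rows).
#' @export
probeModelSurface <- function(model, x1, x2, n = 200, band = c(0.2, 0.8)) {
  probeAxis <- function(v) {
    r <- range(v)
    seq(r[1] + band[1] * diff(r), r[1] + band[2] * diff(r), length.out = n)
  }
  grid <- expand.grid(x1 = probeAxis(x1), x2 = probeAxis(x2))
  names(grid) <- model@predictorNames[1:2]
  z <- predictEnsemble(model, grid)
  data.frame(x1 = grid[[1]], x2 = grid[[2]], z = z)
}
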