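# Kriging of (transformed) regression residuals: ordinary kriging with the
# fitted variogram's covariance, leave-one-out cross-validation, and
# regression kriging for the log-FA surface.

# bordered ordinary-kriging matrix from data locations
okMatrix <- function(model, dataPts) {
  n <- nrow(dataPts)
  C <- modelCovariance(model, geoDistKm(dataPts))
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  A
}

solveKriging <- function(A, B) {
  tryCatch(solve(A, B), error = function(e) {
    # near-singular (e.g. pure-nugget degeneracies): jittered retry
    solve(A + diag(1e-8 * max(abs(diag(A))), nrow(A)), B)
  })
}

# core: ordinary or simple kriging from data points to prediction points
krigePoints <- function(dataPts, z, model, predPts,
                        type = c("ordinary", "simple"), mean0 = 0) {
  type <- match.arg(type)
  dataPts <- as.data.frame(dataPts)[, c("lon", "lat")]
  predPts <- as.data.frame(predPts)[, c("lon", "lat")]
  n <- nrow(dataPts)
  c0 <- sill(model)
  D <- geoDistKm(dataPts, predPts)
  B0 <- modelCovariance(model, D)               # n x m
  if (type == "ordinary") {
    A <- okMatrix(model, dataPts)
    B <- rbind(B0, 1)
    W <- solveKriging(A, B)
    lambda <- W[seq_len(n), , drop = FALSE]
    mu <- W[n + 1, ]
    mean <- as.vector(crossprod(lambda, z))
    var <- c0 - colSums(lambda * B0) - mu
  } else {
    C <- modelCovariance(model, geoDistKm(dataPts))
    lambda <- solveKriging(C, B0)
    mean <- mean0 + as.vector(crossprod(lambda, z - mean0))
    var <- c0 - colSums(lambda * B0)
  }
  list(mean = mean, sd = sqrt(pmax(var, 0)), weights = lambda)
}

#' Krige transformed residuals onto a grid
#'
#' Ordinary kriging (locally estimated mean) of the normal-score
#' transformed regression residuals onto the cells of a grid, using the
#' covariance implied by the fitted variogram model. Below `maxGlobal`
#' data points the full kriging system is solved once (global
#' neighbourhood); above it each cell uses its `nNeighbors` nearest data
#' points. Simple kriging with a fixed mean (default 0, the mean of normal
#' scores) is available via `type`.
#'
#' @param points data.frame with `lon`, `lat` — unique locations.
#' @param values transformed residuals, one per point.
#' @param model a [VariogramModel-class].
#' @param grid a [GridLayer-class] or [GridStack-class] template.
#' @param type `"ordinary"` (default) or `"simple"`.
#' @param mean0 mean for simple kriging.
#' @param maxGlobal global-neighbourhood limit (default 2000 points).
#' @param nNeighbors neighbourhood size beyond `maxGlobal`.
#' @return A [KrigedSurface-class] (`scale = "normal-score"`).
#' @export
krigeResiduals <- function(points, values, model, grid,
                           type = c("ordinary", "simple"), mean0 = 0,
                           maxGlobal = 2000, nNeighbors = 64) {
  type <- match.arg(type)
  pts <- as.data.frame(points)[, c("lon", "lat")]
  stopIfNot(!anyDuplicated(paste(pts$lon, pts$lat)),
            "kriging requires unique point locations")
  template <- if (is(grid, "GridStack")) grid@layers[[1]] else grid
  cc <- cellCentres(template)
  if (nrow(pts) <= maxGlobal) {
    kr <- krigePoints(pts, values, model, cc, type = type, mean0 = mean0)
    mean <- kr$mean; sd <- kr$sd
  } else {
    D <- geoDistKm(pts, cc)
    mean <- sd <- numeric(nrow(cc))
    for (j in seq_len(nrow(cc))) {
      nb <- order(D[, j])[seq_len(min(nNeighbors, nrow(pts)))]
      kr <- krigePoints(pts[nb, ], values[nb], model, cc[j, , drop = FALSE],
                        type = type, mean0 = mean0)
      mean[j] <- kr$mean; sd[j] <- kr$sd
    }
  }
  new("KrigedSurface",
      mean = gridFromVector(template, mean, "kriged_mean"),
      sd = gridFromVector(template, sd, "kriged_sd"),
      scale = "normal-score")
}

#' Leave-one-out cross-validation of a variogram model
#'
#' Kriges every observation from all others under the fitted model and
#' reports the mean error, RMSE and the mean standardised squared error
#' (MSSE, squared errors divided by the kriging variances; near 1 for a
#' well-calibrated model).
#'
#' @param points data.frame with `lon`, `lat` (n >= 10).
#' @param values observations.
#' @param model a [VariogramModel-class].
#' @param type kriging flavour, as in [krigeResiduals()].
#' @return list with `me`, `rmse`, `msse`, and per-point `predicted`,
#'   `sd`.
#' @export
looCrossValidate <- function(points, values, model,
                             type = c("ordinary", "simple")) {
  type <- match.arg(type)
  pts <- as.data.frame(points)[, c("lon", "lat")]
  n <- nrow(pts)
  stopIfNot(n >= 10, "need at least 10 points")
  # Dubrule's shortcut: with the bordered covariance matrix K and
  # B = K^-1, the LOO error at i is (B zz)_i / B_ii and the LOO kriging
  # variance is 1 / B_ii (zz = observations padded with 0 for the
  # unbiasedness row)
  if (type == "ordinary") {
    K <- okMatrix(model, pts)
    B <- tryCatch(solve(K), error = function(e)
      solve(K + diag(1e-8 * max(abs(diag(K))), nrow(K))))
    zz <- c(values, 0)
    err <- (B %*% zz)[seq_len(n)] / diag(B)[seq_len(n)]
    v <- 1 / diag(B)[seq_len(n)]
  } else {
    C <- modelCovariance(model, geoDistKm(pts))
    B <- tryCatch(solve(C), error = function(e)
      solve(C + diag(1e-8 * max(abs(diag(C))), n)))
    err <- (B %*% values)[seq_len(n)] / diag(B)
    v <- 1 / diag(B)
  }
  pred <- values - err
  sdv <- sqrt(pmax(v, 0))
  list(me = mean(err), rmse = sqrt(mean(err^2)),
       msse = mean(err^2 / pmax(v, 1e-12)),
       predicted = pred, sd = sdv)
}

#' Regression kriging of log food availability
#'
#' Fits the multiple linear regression trend by OLS, estimates the residual
#' variogram, kriges the residuals onto the grid and combines trend and
#' residual components: the prediction mean is trend + kriged residual and
#' the prediction standard deviation is the residual kriging standard
#' deviation (the trend is treated as deterministic, mirroring the
#' procedure's uncertainty attribution).
#'
#' @param formula trend formula (e.g. `log(FA) ~ LGP + SCARB`); the
#'   response is on the log scale.
#' @param data data.frame with the response, covariates and `lon`, `lat`.
#' @param stack covariate [GridStack-class] for the trend surface.
#' @param boundaries,cutoff lag specification for the residual variogram.
#' @param shapes candidate variogram shapes.
#' @param ... passed to [krigeResiduals()].
#' @return list of class `RegressionKriging`: `surface`
#'   (a [KrigedSurface-class] on the log scale), `trend` (`MlrFit`),
#'   `variogram` ([VariogramModel-class]), `residualSurface`.
#' @export
regressionKrige <- function(formula, data, stack,
                            boundaries = c(seq(10, 100, 10), 150, 200),
                            cutoff = max(boundaries),
                            shapes = c("spherical", "matern"), ...) {
  trend <- fitMlr(formula, data)
  res <- stats::residuals(trend$lm)
  est <- empiricalVariogram(data[, c("lon", "lat")], res, boundaries, cutoff)
  vgm <- fitVariogramModel(est, shapes)
  ks <- krigeResiduals(data[, c("lon", "lat")], res, vgm, stack, ...)
  trendSurf <- predictSurface(trend, stack)
  mean <- gridFromVector(trendSurf, gridVector(trendSurf) +
                           gridVector(ks@mean), "rk_mean")
  surface <- new("KrigedSurface", mean = mean, sd = ks@sd, scale = "log")
  structure(list(surface = surface, trend = trend, variogram = vgm,
                 residualSurface = ks, empiricalVariogram = est),
            class = "RegressionKriging")
}
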