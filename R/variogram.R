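# Residual spatial structure: normal score transformation, empirical
# variogram by the method of moments, weighted variogram-model fitting and
# nugget-sill diagnostics. Distances are geodesic (great-circle) km on
# WGS84 throughout.

#' Construct a variogram model
#'
#' @param shape `"spherical"` or `"matern"` (smoothness fixed at
#'   `kappa = 0.5`, the exponential model).
#' @param nugget nugget variance (>= 0).
#' @param sill total sill (`>= nugget`); the partial sill is
#'   `sill - nugget`.
#' @param range range parameter in km.
#' @param kappa Matern smoothness (0.5).
#' @return A [VariogramModel-class].
#' @export
variogramModel <- function(shape, nugget, sill, range, kappa = 0.5) {
  stopIfNot(sill >= nugget, "total sill must be >= nugget")
  new("VariogramModel", shape = shape, nugget = nugget,
      psill = sill - nugget, range = range, kappa = kappa)
}

#' @rdname variogramAccessors
#' @export
setGeneric("nugget", function(x) standardGeneric("nugget"))
#' Variogram model accessors
#'
#' `nugget()`, `sill()` (total sill), `practicalRange()` (distance at which
#' ~95% of the sill is reached: the range parameter for the spherical
#' shape, three times it for the exponential), `nuggetSillRatio()`
#' (nugget / total sill) and `spatialFraction()`
#' (`(1 - ratio) * 100`, the percentage of residual variance that is
#' spatially structured).
#'
#' @param x a [VariogramModel-class].
#' @name variogramAccessors
NULL
#' @rdname variogramAccessors
#' @export
setMethod("nugget", "VariogramModel", function(x) x@nugget)
#' @rdname variogramAccessors
#' @export
setGeneric("sill", function(x) standardGeneric("sill"))
#' @rdname variogramAccessors
#' @export
setMethod("sill", "VariogramModel", function(x) x@nugget + x@psill)
#' @rdname variogramAccessors
#' @export
setGeneric("practicalRange", function(x) standardGeneric("practicalRange"))
#' @rdname variogramAccessors
#' @export
setMethod("practicalRange", "VariogramModel", function(x)
  if (x@shape == "matern") 3 * x@range else x@range)

#' @rdname variogramAccessors
#' @export
setGeneric("nuggetSillRatio", function(x) standardGeneric("nuggetSillRatio"))
#' @rdname variogramAccessors
#' @export
setMethod("nuggetSillRatio", "VariogramModel", function(x) {
  s <- sill(x)
  if (s <= 0) {
    warning("total sill is zero; nugget-sill ratio undefined")
    return(NA_real_)
  }
  x@nugget / s
})

#' @rdname variogramAccessors
#' @export
setGeneric("spatialFraction", function(x) standardGeneric("spatialFraction"))
#' @rdname variogramAccessors
#' @export
setMethod("spatialFraction", "VariogramModel", function(x)
  (1 - nuggetSillRatio(x)) * 100)

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "VariogramModel: %s%s, nugget %.4g, sill %.4g, range %.4g km (ratio %.2f)\n",
    object@shape,
    if (object@shape == "matern") sprintf(" (kappa = %g)", object@kappa) else "",
    object@nugget, sill(object), object@range, nuggetSillRatio(object)))
})

#' Model semivariance at given lags
#'
#' @param model a [VariogramModel-class].
#' @param h distances in km (>= 0). At `h = 0` the semivariance is 0 by
#'   convention; the nugget is the limit from the right.
#' @return numeric semivariances.
#' @export
semivariance <- function(model, h) {
  g <- if (model@shape == "spherical") {
    ifelse(h < model@range,
           1.5 * h / model@range - 0.5 * (h / model@range)^3, 1)
  } else {
    1 - exp(-h / model@range)
  }
  ifelse(h == 0, 0, model@nugget + model@psill * g)
}

# covariance function implied by the model (used by kriging):
# C(h) = sill - gamma(h); at h = 0 includes the nugget
modelCovariance <- function(model, h) {
  s <- sill(model)
  ifelse(h == 0, s, s - semivariance(model, h))
}

#' Quantile-based normal score transformation
#'
#' Maps data values to standard-normal scores through their empirical
#' quantiles over `nIntervals` intervals, truncating the tails below the
#' 0.5% and above the 99.5% quantiles to the bounds. The returned map is
#' the monotone piecewise-linear quantile table also used for the inverse
#' transform; ranking ties share the value of their common quantile.
#'
#' @param values numeric data (non-constant; a warning is issued when
#'   `length(values) < nIntervals`).
#' @param nIntervals number of quantile intervals (default 100).
#' @return list with `scores` (transformed values) and `map`
#'   (a [NormalScoreMap-class]).
#' @export
normalScoreTransform <- function(values, nIntervals = 100) {
  stopIfNot(stats::sd(values) > 0, "constant input: no transform exists")
  if (length(values) < nIntervals)
    warning("fewer observations than intervals; quantile table is coarse")
  pLo <- 0.005; pHi <- 0.995
  probs <- seq(pLo, pHi, length.out = nIntervals + 1)
  q <- stats::quantile(values, probs, names = FALSE, type = 7)
  tab <- data.frame(value = q, score = stats::qnorm(probs))
  map <- new("NormalScoreMap", table = tab,
             bounds = c(lower = q[1], upper = q[length(q)]))
  list(scores = applyNormalScore(values, map), map = map)
}

#' @rdname normalScoreTransform
#' @param map a [NormalScoreMap-class] from a prior forward transform.
#' @export
applyNormalScore <- function(values, map) {
  tab <- map@table
  v <- pmin(pmax(values, map@bounds["lower"]), map@bounds["upper"])
  # collapse tied quantile values so interpolation is well defined
  agg <- tapply(tab$score, tab$value, mean)
  xs <- as.numeric(names(agg))
  if (length(xs) < 2) stop("degenerate quantile table", call. = FALSE)
  stats::approx(xs, as.numeric(agg), xout = v, rule = 2)$y
}

#' Inverse normal score transformation
#'
#' Piecewise-linear inverse of the quantile table; scores beyond the
#' mapped range are clamped to the truncation-bound data values.
#'
#' @param scores numeric standard-normal-scale values.
#' @param map a [NormalScoreMap-class].
#' @return data-scale values.
#' @export
inverseNormalScore <- function(scores, map) {
  tab <- map@table
  agg <- tapply(tab$value, tab$score, mean)
  xs <- as.numeric(names(agg))
  stats::approx(xs, as.numeric(agg), xout = scores, rule = 2)$y
}

#' Empirical variogram by the method of moments
#'
#' For every lag bin, half the mean squared difference over all point pairs
#' whose geodesic separation falls in the bin. Default lag boundaries are
#' 10, 20, ..., 100, 150, 200 km with a 200 km cutoff.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param values numeric, one per point.
#' @param boundaries upper lag-bin boundaries in km (first bin starts at 0,
#'   exclusive).
#' @param cutoff maximum pair separation in km.
#' @return data.frame of class `VariogramEstimate` with `lag_upper`,
#'   `dist` (mean pair distance), `gamma`, `np` (pair count); empty bins
#'   keep `np = 0` and `gamma = NA`.
#' @export
empiricalVariogram <- function(points, values,
                               boundaries = c(seq(10, 100, 10), 150, 200),
                               cutoff = max(boundaries)) {
  pts <- as.data.frame(points)
  stopIfNot(nrow(pts) == length(values), "points/values length mismatch")
  h <- geoDistKm(pts[, c("lon", "lat")])
  iu <- which(upper.tri(h))
  d <- h[iu]
  g <- 0.5 * (outer(values, values, "-")^2)[iu]
  keep <- d > 0 & d <= cutoff
  d <- d[keep]; g <- g[keep]
  boundaries <- boundaries[boundaries <= cutoff]
  bin <- findInterval(d, c(0, boundaries), left.open = TRUE,
                      rightmost.closed = FALSE)
  out <- data.frame(lag_upper = boundaries,
                    dist = NA_real_, gamma = NA_real_, np = 0L)
  for (b in seq_along(boundaries)) {
    sel <- bin == b
    out$np[b] <- sum(sel)
    if (out$np[b] > 0) {
      out$dist[b] <- mean(d[sel])
      out$gamma[b] <- mean(g[sel])
    }
  }
  class(out) <- c("VariogramEstimate", "data.frame")
  out
}

#' Fit a variogram model to an empirical variogram
#'
#' For each candidate shape, minimises the weighted sum of squared errors
#' between empirical and model semivariances with weights `N_j / h_j^2`
#' (pair count over squared mean distance per bin), subject to
#' `nugget >= 0` and `partial sill >= 0`; the shape with the smallest
#' weighted SSE wins. Multistart L-BFGS-B on (nugget, partial sill, range).
#'
#' @param estimate a `VariogramEstimate` from [empiricalVariogram()] with
#'   at least 3 non-empty bins.
#' @param shapes candidate shapes (default spherical and Matern
#'   kappa = 0.5).
#' @return The best-fitting [VariogramModel-class]; its `"wsse"` and
#'   `"converged"` attributes carry the fit diagnostics.
#' @export
fitVariogramModel <- function(estimate, shapes = c("spherical", "matern")) {
  est <- estimate[estimate$np > 0 & is.finite(estimate$gamma), ]
  stopIfNot(nrow(est) >= 3, "need at least 3 non-empty lag bins")
  w <- est$np / est$dist^2
  gbar <- max(est$gamma)
  hmax <- max(est$dist)
  best <- NULL
  for (shape in shapes) {
    obj <- function(p) {
      m <- new("VariogramModel", shape = shape, nugget = p[1], psill = p[2],
               range = p[3], kappa = 0.5)
      sum(w * (est$gamma - semivariance(m, est$dist))^2)
    }
    starts <- list(
      c(est$gamma[1] * 0.5, gbar - est$gamma[1] * 0.5, hmax / 3),
      c(est$gamma[1] * 0.9, max(gbar - est$gamma[1] * 0.9, 1e-6), hmax / 6),
      c(1e-6, gbar, hmax / 2),
      c(gbar * 0.8, gbar * 0.2, hmax))
    for (s in starts) {
      s <- pmax(s, c(0, 1e-9, 1e-3))
      opt <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B",
                     lower = c(0, 0, 1e-3),
                     upper = c(2 * gbar, 4 * gbar, 10 * hmax),
                     control = list(maxit = 1000, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value)
        best <- list(value = opt$value, par = opt$par, shape = shape,
                     converged = opt$convergence == 0)
    }
  }
  if (is.null(best)) stop("variogram model fitting failed for all shapes",
                          call. = FALSE)
  m <- new("VariogramModel", shape = best$shape, nugget = best$par[1],
           psill = best$par[2], range = best$par[3], kappa = 0.5)
  # a range below the shortest observed lag is unidentifiable: the model is
  # then indistinguishable from pure nugget, so report it as such
  if (m@range < min(est$dist)) {
    g0 <- sum(w * est$gamma) / sum(w)
    m <- new("VariogramModel", shape = best$shape, nugget = g0, psill = 0,
             range = min(est$dist), kappa = 0.5)
    attr(m, "wsse") <- sum(w * (est$gamma - g0)^2)
    attr(m, "converged") <- best$converged
    return(m)
  }
  attr(m, "wsse") <- best$value
  attr(m, "converged") <- best$converged
  m
}

#' Flag indicators with spatially structured residuals
#'
#' Applies the nugget-sill-ratio rule: an indicator shows spatial
#' autocorrelation when its residual variogram's nugget-sill ratio is at
#' most `threshold` (default 0.7).
#'
#' @param models named list of [VariogramModel-class] objects (or a named
#'   numeric vector of ratios).
#' @param threshold ratio threshold (default 0.7).
#' @return list with `flagged` (names), `count` and `ratios`.
#' @export
classifySpatialStructure <- function(models, threshold = 0.7) {
  ratios <- if (is.numeric(models)) models
            else vapply(models, nuggetSillRatio, 0)
  flagged <- names(ratios)[!is.na(ratios) & ratios <= threshold]
  list(flagged = flagged, count = length(flagged), ratios = ratios)
}
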