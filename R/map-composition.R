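# Final map composition: back-transformations, 95% prediction-interval
# bounds, and addition of trend and residual surfaces with clamping of
# proportion maps to [0, 1].

gridOp <- function(a, b, f, name) {
  stopIfNot(identical(dim(a@values), dim(b@values)) &&
              isTRUE(all.equal(c(a@xmin, a@ymin, a@cellsize),
                               c(b@xmin, b@ymin, b@cellsize))),
            "grid mismatch")
  gridLayer(name, f(a@values, b@values), a@xmin, a@ymin, a@cellsize)
}

clampValues <- function(v, scale) {
  if (scale == "proportion") pmin(pmax(v, 0), 1) else pmax(v, 0)
}

#' Back-transform a log-scale mean surface to the lognormal median
#'
#' `E(Y) = exp(mu)` cell-wise: the back-transformed kriging mean of a
#' log-transformed variable is the median (not the mean) of the lognormal
#' predictive distribution.
#'
#' @param mu a [GridLayer-class] on the log scale.
#' @return A [GridLayer-class] on the data scale.
#' @export
backtransformLognormalMedian <- function(mu)
  gridLayer("median", exp(mu@values), mu@xmin, mu@ymin, mu@cellsize)

#' 95% prediction-interval bounds for the log-scale (MLR) surface
#'
#' `lower = exp(mu - 1.96 sigma)`, `upper = exp(mu + 1.96 sigma)`
#' cell-wise; by log symmetry `upper / median = median / lower`.
#'
#' @param mu,sigma [GridLayer-class] mean and standard deviation on the
#'   log scale (`sigma >= 0`).
#' @return list with `lower`, `upper` [GridLayer-class] surfaces.
#' @export
mlrPiBounds <- function(mu, sigma) {
  stopIfNot(all(sigma@values >= 0, na.rm = TRUE), "sigma must be >= 0")
  list(lower = gridOp(mu, sigma, function(m, s) exp(m - 1.96 * s), "pi_lower"),
       upper = gridOp(mu, sigma, function(m, s) exp(m + 1.96 * s), "pi_upper"))
}

#' Back-transformed residual median and 95% PI bounds (MIBR path)
#'
#' On the normal-score scale the three surfaces are `mu`, `mu - 1.96 sigma`
#' and `mu + 1.96 sigma`; each is back-transformed through the inverse
#' normal score map, so the kriging mean becomes the median of the
#' back-transformed residuals and the ordering is preserved by
#' monotonicity.
#'
#' @param kriged a [KrigedSurface-class] on the normal-score scale.
#' @param map the [NormalScoreMap-class] from the forward transform.
#' @return list of [GridLayer-class]: `median`, `lower`, `upper` on the
#'   residual data scale.
#' @export
mibrPiBounds <- function(kriged, map) {
  m <- kriged@mean@values
  s <- kriged@sd@values
  tmpl <- kriged@mean
  back <- function(x, name) {
    v <- x
    ok <- is.finite(x)
    v[ok] <- inverseNormalScore(x[ok], map)
    gridLayer(name, v, tmpl@xmin, tmpl@ymin, tmpl@cellsize)
  }
  list(median = back(m, "resid_median"),
       lower = back(m - 1.96 * s, "resid_lower"),
       upper = back(m + 1.96 * s, "resid_upper"))
}

#' Compose a final indicator map
#'
#' Adds the regression prediction surface and the back-transformed median
#' residual surface cell-wise; proportion-scale maps are clamped to
#' \[0, 1\] after the addition (values above 1 set to 1, below 0 set to 0),
#' FA-scale maps to non-negative values.
#'
#' @param prediction,residualMedian [GridLayer-class] surfaces on a common
#'   grid.
#' @param scale `"proportion"` or `"kcal"`.
#' @return A [GridLayer-class].
#' @export
composeFinalMap <- function(prediction, residualMedian,
                            scale = c("proportion", "kcal")) {
  scale <- match.arg(scale)
  gridOp(prediction, residualMedian,
         function(p, r) clampValues(p + r, scale), "final")
}

#' Compose 95% prediction-interval maps
#'
#' Adds the prediction surface to the lower and upper back-transformed
#' residual bounds, clamps to the valid range, and enforces the cell-wise
#' ordering lower <= median <= upper.
#'
#' @param prediction [GridLayer-class] regression prediction surface.
#' @param residual list with `median`, `lower`, `upper` from
#'   [mibrPiBounds()].
#' @param scale `"proportion"` or `"kcal"`.
#' @return list of class `UncertaintyMaps` with `median`, `lower`,
#'   `upper` [GridLayer-class] surfaces and the `scale` tag.
#' @export
composePiMaps <- function(prediction, residual,
                          scale = c("proportion", "kcal")) {
  scale <- match.arg(scale)
  med <- composeFinalMap(prediction, residual$median, scale)
  lo <- gridOp(prediction, residual$lower,
               function(p, r) clampValues(p + r, scale), "pi_lower")
  up <- gridOp(prediction, residual$upper,
               function(p, r) clampValues(p + r, scale), "pi_upper")
  lo@values <- pmin(lo@values, med@values)
  up@values <- pmax(up@values, med@values)
  structure(list(median = med, lower = lo, upper = up, scale = scale),
            class = "UncertaintyMaps")
}
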