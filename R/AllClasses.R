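#' @import methods
NULL

#' Single raster layer on a regular geographic grid
#'
#' A named 2-D layer of values on a regular lon/lat (WGS84) grid. Rows run
#' from north (row 1) to south, columns from west to east; missing cells are
#' `NA`. Cell membership follows the half-open convention
#' `[x, x + dx) x (y - dy, y]` so a point on a shared edge belongs to exactly
#' one cell.
#'
#' @slot name layer name.
#' @slot values numeric matrix of cell values (`NA` = nodata).
#' @slot xmin,ymin western / southern edge of the grid (degrees).
#' @slot cellsize cell size in degrees (square cells).
#' @exportClass GridLayer
setClass("GridLayer",
  representation(name = "character", values = "matrix",
                 xmin = "numeric", ymin = "numeric", cellsize = "numeric"),
  validity = function(object) {
    if (length(object@cellsize) != 1 || object@cellsize <= 0)
      return("cellsize must be a single positive number")
    if (!is.numeric(object@values)) return("values must be numeric")
    TRUE
  })

#' Stack of raster layers sharing one grid geometry
#'
#' @slot layers named list of [GridLayer-class] objects on identical grids.
#' @exportClass GridStack
setClass("GridStack",
  representation(layers = "list"),
  validity = function(object) {
    if (length(object@layers) == 0) return("empty stack")
    if (!all(vapply(object@layers, is, TRUE, "GridLayer")))
      return("all elements must be GridLayer objects")
    g1 <- object@layers[[1]]
    for (l in object@layers) {
      if (!identical(dim(l@values), dim(g1@values)) ||
          !isTRUE(all.equal(c(l@xmin, l@ymin, l@cellsize),
                            c(g1@xmin, g1@ymin, g1@cellsize))))
        return("all layers must share the same grid geometry")
    }
    TRUE
  })

#' Parametric variogram model
#'
#' Semivariance model with a nugget, a partial sill and a range. Supported
#' shapes are `"spherical"` and `"matern"` with fixed smoothness
#' `kappa = 0.5` (the exponential model). For the exponential shape the
#' `range` slot is the distance parameter; the practical range (95% of the
#' sill) is about three times this value.
#'
#' @slot shape `"spherical"` or `"matern"`.
#' @slot nugget nugget variance (>= 0).
#' @slot psill partial sill, so the total sill is `nugget + psill`.
#' @slot range range parameter in km (> 0).
#' @slot kappa Matern smoothness (fixed at 0.5; ignored for spherical).
#' @exportClass VariogramModel
setClass("VariogramModel",
  representation(shape = "character", nugget = "numeric", psill = "numeric",
                 range = "numeric", kappa = "numeric"),
  validity = function(object) {
    if (!object@shape %in% c("spherical", "matern"))
      return("shape must be 'spherical' or 'matern'")
    if (object@nugget < 0) return("nugget must be >= 0")
    if (object@psill < 0) return("partial sill must be >= 0")
    if (object@range <= 0) return("range must be > 0")
    TRUE
  })

#' Quantile table of a normal score transformation
#'
#' Monotone piecewise-linear map between data values and standard-normal
#' scores, built from empirical quantiles over a fixed number of intervals,
#' with the tails below the 0.5% and above the 99.5% quantiles truncated to
#' the bounds.
#'
#' @slot table data.frame with columns `value` and `score`, both
#'   non-decreasing.
#' @slot bounds data-scale truncation bounds (0.5% and 99.5% quantiles).
#' @exportClass NormalScoreMap
setClass("NormalScoreMap",
  representation(table = "data.frame", bounds = "numeric"),
  validity = function(object) {
    if (!all(c("value", "score") %in% names(object@table)))
      return("table needs 'value' and 'score' columns")
    if (is.unsorted(object@table$value) || is.unsorted(object@table$score))
      return("quantile table must be monotone non-decreasing")
    TRUE
  })

#' Kriged surface: interpolation mean and standard deviation
#'
#' Gridded kriging prediction, carrying the interpolated mean and the
#' kriging standard deviation on the scale of the interpolated variable
#' (normal scores for inflated-beta residuals, log scale for FA).
#'
#' @slot mean,sd [GridLayer-class] objects on a common grid.
#' @slot scale free-text tag for the value scale (e.g. `"normal-score"`,
#'   `"log"`).
#' @exportClass KrigedSurface
setClass("KrigedSurface",
  representation(mean = "GridLayer", sd = "GridLayer", scale = "character"),
  validity = function(object) {
    if (!identical(dim(object@mean@values), dim(object@sd@values)))
      return("mean and sd grids must match")
    if (any(object@sd@values < -1e-8, na.rm = TRUE))
      return("kriging standard deviation must be non-negative")
    TRUE
  })

#' Fitted zero-and-one-inflated beta regression model
#'
#' Maximum-likelihood fit of the mixed discrete-continuous distribution with
#' point masses at 0 and 1 and a Beta(alpha, beta) density on (0,1),
#' parameterised by mu, sigma (beta shape via `beinfShape()`), nu and tau
#' (inflation odds via `beinfProbs()`). Each distribution parameter has its
#' own linear predictor: logit link for mu and sigma, log link for nu and
#' tau. The `"MIBR0"` family drops tau (no one-inflation).
#'
#' @slot family `"MIBR"` or `"MIBR0"`.
#' @slot coefficients named list of link-scale coefficient vectors per
#'   distribution parameter.
#' @slot se standard errors, same shape as `coefficients`.
#' @slot vcov joint variance-covariance matrix from the observed information.
#' @slot loglik maximised log-likelihood.
#' @slot aic Akaike information criterion, `-2 loglik + 2k`.
#' @slot converged optimiser convergence flag.
#' @slot fitted fitted expectations E(y) per observation.
#' @slot y observed response.
#' @slot trace character vector recording the order in which terms were
#'   added during stepwise selection (`"<param>:<covariate>"`), used by the
#'   simplification rule.
#' @exportClass InflatedBetaFit
setClass("InflatedBetaFit",
  representation(family = "character", coefficients = "list", se = "list",
                 vcov = "matrix", loglik = "numeric", aic = "numeric",
                 converged = "logical", fitted = "numeric", y = "numeric",
                 trace = "character"),
  validity = function(object) {
    if (!object@family %in% c("MIBR", "MIBR0"))
      return("family must be 'MIBR' or 'MIBR0'")
    if (object@family == "MIBR0" && "tau" %in% names(object@coefficients))
      return("MIBR0 fits carry no tau coefficients")
    TRUE
  })

setOldClass("MlrFit")
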