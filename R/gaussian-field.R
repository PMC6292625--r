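# Stationary Gaussian random field simulation at arbitrary lon/lat points.
#
# Two methods: exact Cholesky factorisation of the covariance matrix for
# small point sets, and a random-Fourier-feature (spectral) approximation
# for large ones. The cutoff is 5000 points: below it exactness is cheap,
# above it the O(n^3) factorisation dominates.

# correlation function with a *practical* range in km: correlation drops to
# ~0.05 at h = range for both shapes
grfCorrelation <- function(h, range_km, shape = "matern") {
  switch(shape,
    matern = exp(-3 * h / range_km),       # kappa = 0.5 (exponential)
    spherical = ifelse(h < range_km,
                       1 - 1.5 * h / range_km + 0.5 * (h / range_km)^3, 0),
    stop("unknown shape: ", shape))
}

#' Simulate a Gaussian random field at point locations
#'
#' Draws one realisation of a zero-mean, unit-variance stationary Gaussian
#' field with the given correlation shape and practical range, at arbitrary
#' lon/lat points (geodesic distances). Exact Cholesky simulation below
#' 5000 points; a random-Fourier-feature spectral approximation above.
#'
#' @param points data.frame/matrix with `lon`, `lat`.
#' @param rangeKm practical correlation range in km (> 0).
#' @param shape `"matern"` (kappa = 0.5, i.e. exponential) or `"spherical"`.
#' @param seed integer seed; identical seeds give identical fields.
#' @param method `"auto"`, `"cholesky"` or `"spectral"`.
#' @param nFeatures number of random Fourier features for the spectral
#'   method.
#' @return numeric vector, one value per point.
#' @export
simulateGaussianField <- function(points, rangeKm, shape = "matern", seed = 1,
                                  method = c("auto", "cholesky", "spectral"),
                                  nFeatures = 512) {
  stopIfNot(rangeKm > 0, "rangeKm must be > 0")
  method <- match.arg(method)
  pts <- as.matrix(as.data.frame(points)[, c("lon", "lat")])
  n <- nrow(pts)
  if (method == "auto") method <- if (n <= 5000) "cholesky" else "spectral"
  set.seed(seed)
  if (method == "cholesky") {
    h <- geoDistKm(pts)
    C <- grfCorrelation(h, rangeKm, shape)
    diag(C) <- 1 + 1e-8                      # numerical jitter
    L <- chol(C)
    as.vector(crossprod(L, stats::rnorm(n)))
  } else {
    # planar approximation in km around the centroid; adequate for the
    # country-scale extents the generator targets
    lat0 <- mean(pts[, "lat"])
    xy <- cbind((pts[, "lon"] - mean(pts[, "lon"])) * 111.32 * cos(lat0 * pi / 180),
                (pts[, "lat"] - lat0) * 111.32)
    # 2-D spectral measure of the exponential correlation: radial CDF
    # F(r) = 1 - (1 + a^2 r^2)^(-1/2); sample by inversion (spherical shape
    # is approximated by the exponential with the same practical range)
    a <- rangeKm / 3
    u <- stats::runif(nFeatures)
    r <- sqrt((1 - u)^-2 - 1) / a
    theta <- stats::runif(nFeatures, 0, 2 * pi)
    W <- cbind(r * cos(theta), r * sin(theta))
    phi <- stats::runif(nFeatures, 0, 2 * pi)
    proj <- xy %*% t(W) + matrix(phi, n, nFeatures, byrow = TRUE)
    sqrt(2 / nFeatures) * rowSums(cos(proj))
  }
}
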