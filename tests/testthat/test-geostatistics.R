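test_that("normal score transform is monotone, centred and invertible", {
  set.seed(1)
  x <- runif(10000)
  nst <- normalScoreTransform(x)
  expect_lt(abs(mean(nst$scores)), 0.05)
  expect_true(sd(nst$scores) > 0.9 && sd(nst$scores) < 1.1)
  # median maps near zero
  medScore <- applyNormalScore(median(x), nst$map)
  expect_lt(abs(medScore), qnorm(0.505) - qnorm(0.495) + 0.05)
  # monotone in the input
  ord <- order(x)
  expect_true(all(diff(nst$scores[ord]) >= -1e-12))
  # round trip for interior (non-truncated) values
  interior <- x > quantile(x, 0.01) & x < quantile(x, 0.99)
  back <- inverseNormalScore(nst$scores[interior], nst$map)
  qw <- max(diff(nst$map@table$value))
  expect_lt(max(abs(back - x[interior])), qw + 1e-9)
  # score 0 inverts to the data median, scores beyond bounds clamp
  expect_lt(abs(inverseNormalScore(0, nst$map) - median(x)), qw)
  expect_equal(inverseNormalScore(10, nst$map),
               unname(nst$map@bounds["upper"]))
  expect_error(normalScoreTransform(rep(1, 50)), "constant")
})

test_that("empirical variogram equals brute-force pair enumeration", {
  set.seed(2)
  pts <- data.frame(lon = runif(60, 30, 31), lat = runif(60, 0, 1))
  z <- rnorm(60)
  bounds <- c(seq(10, 100, 10), 150, 200)
  est <- empiricalVariogram(pts, z, bounds)
  # brute force
  D <- famap:::geoDistKm(pts)
  acc <- matrix(0, length(bounds), 2)
  for (i in 1:59) for (j in (i + 1):60) {
    d <- D[i, j]
    if (d <= 0 || d > 200) next
    b <- which(d <= bounds)[1]
    if (d <= c(0, bounds)[b]) b <- b  # half-open bins (lower, upper]
    acc[b, 1] <- acc[b, 1] + 0.5 * (z[i] - z[j])^2
    acc[b, 2] <- acc[b, 2] + 1
  }
  expect_equal(est$np, as.integer(acc[, 2]))
  nz <- acc[, 2] > 0
  expect_equal(est$gamma[nz], acc[nz, 1] / acc[nz, 2], tolerance = 1e-12)

  # three collinear points: hand-enumerated bins
  eq <- 30 / (6378.137 * pi / 180)     # ~30 km along the equator
  p3 <- data.frame(lon = c(30, 30 + 0.97 * eq, 30 + 1.94 * eq), lat = 0)
  e3 <- empiricalVariogram(p3, c(0, 1, 0), bounds)
  expect_equal(e3$np[e3$lag_upper == 30], 2L)  # two ~29 km pairs
  expect_equal(e3$gamma[e3$lag_upper == 30], 0.5)
  expect_equal(e3$np[e3$lag_upper == 60], 1L)
  expect_equal(e3$gamma[e3$lag_upper == 60], 0)

  # constant field: all semivariances zero
  ec <- empiricalVariogram(pts, rep(1, 60), bounds)
  expect_true(all(ec$gamma[ec$np > 0] == 0))

  # co-located duplicates leave positive-lag bins unchanged
  dup <- rbind(pts, pts)
  ed <- empiricalVariogram(dup, c(z, z), bounds)
  expect_equal(ed$gamma[ed$np > 0], est$gamma[est$np > 0], tolerance = 1e-12)
})

test_that("variogram model fitting recovers exact and degenerate inputs", {
  truth <- variogramModel("spherical", nugget = 0.3, sill = 1.0, range = 50)
  est <- data.frame(lag_upper = seq(10, 120, 10), dist = seq(5, 115, 10),
                    np = 100L)
  est$gamma <- semivariance(truth, est$dist)
  class(est) <- c("VariogramEstimate", "data.frame")
  fit <- fitVariogramModel(est)
  expect_equal(fit@shape, "spherical")
  expect_equal(nugget(fit), 0.3, tolerance = 1e-3)
  expect_equal(sill(fit), 1.0, tolerance = 1e-3)
  expect_equal(fit@range, 50, tolerance = 0.05)

  # white noise: fitted ratio near 1; the pair-count/distance^2 weighting
  # can chase a low first bin in single replicates, so test the median
  ratios <- vapply(1:5, function(s) {
    set.seed(s)
    pts <- data.frame(lon = runif(800, 30, 32), lat = runif(800, 0, 2))
    ew <- empiricalVariogram(pts, rnorm(800), c(seq(10, 100, 10), 150, 200))
    nuggetSillRatio(fitVariogramModel(ew))
  }, 0)
  expect_gt(median(ratios), 0.9)

  # model curve limits: nugget at 0+, sill far out
  expect_equal(semivariance(truth, 1e-9), 0.3, tolerance = 1e-6)
  expect_equal(semivariance(truth, 1e6), 1.0)
  expm <- variogramModel("matern", 0.2, 1, 30)
  expect_lt(abs(semivariance(expm, 300) - 1), 1e-4)
  expect_equal(semivariance(expm, 0), 0)     # exact zero at h = 0
})

test_that("nugget-sill diagnostics follow their definitions", {
  m <- variogramModel("matern", nugget = 1.32, sill = 1.61, range = 87)
  expect_equal(round(nuggetSillRatio(m), 2), 0.82)
  m2 <- variogramModel("matern", nugget = 0.52, sill = 0.91, range = 175)
  expect_equal(round(nuggetSillRatio(m2), 2), 0.57)
  m0 <- variogramModel("spherical", nugget = 0, sill = 1, range = 10)
  expect_equal(nuggetSillRatio(m0), 0)
  expect_equal(spatialFraction(m0), 100)

  models <- list(a = m, b = m0)
  cls <- classifySpatialStructure(models)
  expect_equal(cls$flagged, "b")
  expect_equal(classifySpatialStructure(c(x = 1, y = 1))$count, 0)
  expect_equal(classifySpatialStructure(c(x = 0.9, y = 0.2), 1.0)$count, 2)
})

test_that("kriging interpolates exactly, weights sum to one, variance is data-free", {
  set.seed(4)
  pts <- data.frame(lon = runif(30, 30, 31), lat = runif(30, 0, 1))
  z <- rnorm(30)
  vg <- variogramModel("matern", nugget = 0, sill = 1, range = 20)
  kr <- famap:::krigePoints(pts, z, vg, pts)
  expect_lt(max(abs(kr$mean - z)), 1e-6)
  expect_lt(max(kr$sd), 1e-4)

  # weights sum to 1 at arbitrary prediction points (ordinary kriging)
  newp <- data.frame(lon = runif(10, 30, 31), lat = runif(10, 0, 1))
  kr2 <- famap:::krigePoints(pts, z, vg, newp)
  expect_equal(colSums(kr2$weights), rep(1, 10), tolerance = 1e-8)

  # far beyond the range: mean near the stationary mean, variance near sill
  far <- data.frame(lon = 80, lat = 40)
  kr3 <- famap:::krigePoints(pts, z, vg, far)
  expect_lt(abs(kr3$mean - mean(z)), 0.05 + abs(mean(z)) * 0.1)
  expect_gt(kr3$sd^2, 0.99)

  # kriging variance depends on locations and model only
  kr4 <- famap:::krigePoints(pts, sample(z), vg, newp)
  expect_equal(kr4$sd, kr2$sd, tolerance = 1e-12)
})

test_that("two-point kriging weights match the hand-solved system", {
  vg <- variogramModel("matern", nugget = 0.1, sill = 1, range = 25)
  pts <- data.frame(lon = c(30, 30.4), lat = c(0, 0))
  z <- c(1, 2)
  p0 <- data.frame(lon = 30.1, lat = 0)
  kr <- famap:::krigePoints(pts, z, vg, p0)
  # hand-built 3x3 ordinary kriging system
  h12 <- famap:::geoDistKm(pts)[1, 2]
  c0 <- sill(vg)
  cfun <- function(h) ifelse(h == 0, c0, c0 - semivariance(vg, h))
  A <- rbind(c(cfun(0), cfun(h12), 1),
             c(cfun(h12), cfun(0), 1),
             c(1, 1, 0))
  b <- c(cfun(famap:::geoDistKm(pts, p0))[, 1], 1)
  w <- solve(A, b)
  expect_equal(as.vector(kr$weights), w[1:2], tolerance = 1e-8)
  expect_equal(kr$mean, sum(w[1:2] * z), tolerance = 1e-8)
})

test_that("leave-one-out cross-validation is calibrated on self-simulated data", {
  set.seed(5)
  n <- 500
  pts <- data.frame(lon = runif(n, 30, 32), lat = runif(n, 0, 2))
  vg <- variogramModel("matern", nugget = 0.3, sill = 1, range = 60 / 3)
  z <- sqrt(vg@psill) *
    simulateGaussianField(pts, practicalRange(vg), seed = 6) +
    sqrt(vg@nugget) * rnorm(n)
  cv <- looCrossValidate(pts, z, vg)
  expect_gt(cv$msse, 0.7); expect_lt(cv$msse, 1.3)
  expect_lt(abs(cv$me), 0.1)

  # pure nugget on a constant field: zero mean error
  vgn <- variogramModel("spherical", nugget = 1, sill = 1.000001, range = 10)
  cvn <- looCrossValidate(pts[1:50, ], rep(5, 50), vgn)
  expect_lt(abs(cvn$me), 1e-8)

  # order invariance
  p <- sample(n)
  cvp <- looCrossValidate(pts[p, ], z[p], vg)
  expect_equal(cvp$msse, cv$msse, tolerance = 1e-9)
})

test_that("nugget-sill ratio is recovered from simulated Gaussian fields", {
  # spherical truth, ratio 0.3; median of replicates within +/-0.15
  truthRatio <- 0.3
  ratios <- vapply(1:5, function(r) {
    set.seed(100 + r)
    n <- 700
    pts <- data.frame(lon = runif(n, 30, 33), lat = runif(n, 0, 3))
    z <- sqrt(0.7) * simulateGaussianField(pts, 80, shape = "spherical",
                                           seed = 200 + r) +
      sqrt(0.3) * rnorm(n)
    est <- empiricalVariogram(pts, z)
    nuggetSillRatio(fitVariogramModel(est))
  }, 0)
  expect_lt(abs(median(ratios) - truthRatio), 0.15)
})

test_that("kriged surfaces and regression kriging behave sensibly", {
  st <- makeTestStack(seed = 41)
  set.seed(7)
  n <- 200
  pts <- data.frame(lon = runif(n, 30.02, 30.98), lat = runif(n, 0.02, 0.98))
  covs <- sampleAtPoints(st, pts)
  y <- 5 + 0.002 * covs$RAIN +
    0.5 * simulateGaussianField(pts, 40, seed = 8) + 0.2 * rnorm(n)
  d <- cbind(data.frame(y = y), covs, pts)
  rk <- regressionKrige(y ~ RAIN, d, st,
                        boundaries = seq(5, 60, 5), cutoff = 60)
  expect_s4_class(rk$surface, "KrigedSurface")
  expect_true(all(gridValues(rk$surface@sd) >= 0))
  # in-sample: regression kriging honours the data better than trend alone
  smp <- sampleAtPoints(gridStack(list(rk$surface@mean)), pts)
  trend <- predictSurface(rk$trend, st)
  tsmp <- sampleAtPoints(gridStack(list(trend)), pts)
  rmseRk <- sqrt(mean((smp[[1]] - y)^2))
  rmseTr <- sqrt(mean((tsmp[[1]] - y)^2))
  expect_lt(rmseRk, rmseTr)

  # deterministic under fixed inputs
  rk2 <- regressionKrige(y ~ RAIN, d, st,
                         boundaries = seq(5, 60, 5), cutoff = 60)
  expect_identical(gridValues(rk2$surface@mean), gridValues(rk$surface@mean))

  # duplicate locations are rejected
  expect_error(krigeResiduals(rbind(pts, pts[1, ]), c(y, 1),
                              rk$variogram, st), "unique")
})
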