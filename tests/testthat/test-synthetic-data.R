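test_that("covariate raster generation is deterministic and respects specs", {
  specs <- data.frame(name = c("A", "B"), mean = c(10, 5), sd = c(2, 0),
                      range_km = c(50, 50))
  s1 <- generateCovariateRasters(c(30, 31, 0, 1), 0.05, specs, seed = 7)
  s2 <- generateCovariateRasters(c(30, 31, 0, 1), 0.05, specs, seed = 7)
  expect_identical(gridValues(s1), gridValues(s2))
  expect_equal(dim(gridValues(s1)$A), c(20, 20))
  # sd = 0 gives a constant layer at its mean
  expect_true(all(gridValues(s1)$B == 5))
  expect_error(generateCovariateRasters(c(30, 30, 0, 1), 0.05, specs),
               "extent")
  expect_error(generateCovariateRasters(c(30, 31, 0, 1), -1, specs),
               "resolution")
})

test_that("generated fields have the requested marginal moments and range", {
  specs <- data.frame(name = "X", mean = 1000, sd = 200, range_km = 50)
  st <- generateCovariateRasters(c(30, 33, 0, 3), 0.075, specs, seed = 12)
  v <- as.vector(gridValues(st)$X)
  # mean within 3 standard errors accounting for spatial correlation:
  # effective n is roughly (extent / range)^2 = (333/50)^2 ~ 44
  se_eff <- 200 / sqrt(44)
  expect_lt(abs(mean(v) - 1000), 3 * se_eff)
  expect_lt(abs(sd(v) - 200) / 200, 0.5)
  # re-estimated variogram range within +/-40% of the requested 50 km;
  # single realisations of a field spanning ~6 ranges estimate the range
  # noisily, so the check uses the median over four independent fields
  ranges <- vapply(12:15, function(s) {
    sti <- generateCovariateRasters(c(30, 33, 0, 3), 0.075, specs, seed = s)
    vi <- as.vector(gridValues(sti)$X)
    est <- empiricalVariogram(cellCentres(sti), vi,
                              boundaries = seq(10, 120, 10), cutoff = 120)
    practicalRange(fitVariogramModel(est, "matern"))
  }, 0)
  expect_lt(abs(median(ranges) - 50) / 50, 0.4)
})

test_that("enumeration-area sampling clusters households", {
  pts <- generateEnumerationAreas(1, 1, c(30, 31, 0, 1), seed = 5)
  expect_equal(nrow(pts), 1)
  expect_true(pts$lon >= 30 && pts$lon <= 31)

  pts <- generateEnumerationAreas(10, 10, c(30, 32, 0, 2), clusterSdKm = 2,
                                  seed = 5)
  expect_equal(nrow(pts), 100)
  D <- famap:::geoDistKm(pts[, c("lon", "lat")])
  same <- outer(pts$ea, pts$ea, "==") & upper.tri(D)
  diff <- !outer(pts$ea, pts$ea, "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))

  pts0 <- generateEnumerationAreas(3, 4, c(30, 32, 0, 2), clusterSdKm = 0,
                                   seed = 5)
  expect_equal(nrow(unique(pts0[, c("lon", "lat")])), 3)
})

test_that("privacy displacement stays within the offset bound", {
  pts <- data.frame(lon = runif(500, 30, 32), lat = runif(500, 0, 2))
  expect_identical(displaceForPrivacy(pts, 0, seed = 1), pts)
  moved <- displaceForPrivacy(pts, 10, seed = 2)
  d <- diag(famap:::geoDistKm(pts, moved))
  expect_true(all(d <= 10 + 1e-9))
  expect_gt(max(d), 5)
  expect_identical(moved, displaceForPrivacy(pts, 10, seed = 2))
})

test_that("inflated-beta field simulation matches its target law", {
  st <- makeTestStack()
  set.seed(3)
  pts <- data.frame(lon = runif(2000, 30.05, 30.95),
                    lat = runif(2000, 0.05, 0.95))
  # no inflation: nu, tau effectively zero
  tr0 <- syntheticTruth(
    coefficients = list(mu = c("(Intercept)" = 0),
                        sigma = c("(Intercept)" = famap:::logit(0.3)),
                        nu = c("(Intercept)" = -30),
                        tau = c("(Intercept)" = -30)),
    residualVariogram = variogramModel("matern", 0, 1e-6, 50),
    residualScale = c(mu = 0, sigma = 0, nu = 0, tau = 0))
  y0 <- simulateInflatedBetaField(pts[1:1000, ], st, tr0, seed = 4)$y
  expect_true(all(y0 > 0 & y0 < 1))

  # constant P0 = 0.3, P1 = 0.1: nu = 0.5, tau = 1/6 over denominator 5/3
  tr <- syntheticTruth(
    coefficients = list(mu = c("(Intercept)" = 0),
                        sigma = c("(Intercept)" = famap:::logit(0.3)),
                        nu = c("(Intercept)" = log(0.5)),
                        tau = c("(Intercept)" = log(1 / 6))),
    residualVariogram = variogramModel("matern", 0, 1e-6, 50),
    residualScale = c(mu = 0, sigma = 0, nu = 0, tau = 0))
  sim <- simulateInflatedBetaField(pts, st, tr, seed = 5)
  expect_equal(unique(round(sim$params$nu, 10)), 0.5)
  se0 <- sqrt(0.3 * 0.7 / 2000)
  se1 <- sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(mean(sim$y == 0) - 0.3), 3 * se0)
  expect_lt(abs(mean(sim$y == 1) - 0.1), 3 * se1)
  # Monte-Carlo mean vs closed form (tau + mu)/(1 + nu + tau)
  ey <- beinfExpectation(0.5, 0.5, 1 / 6)
  expect_lt(abs(mean(sim$y) - ey), 3 * sd(sim$y) / sqrt(2000))
})

test_that("survey inversion reproduces target FA and shares", {
  # single adult male, 100% maize consumption, FA 2500:
  # production must carry 2500 * 365 = 912500 kcal
  et <- unitEnergyTable()
  loc <- data.frame(lon = 30, lat = 0)
  hh <- simulateSurveyResponses(loc, data.frame(maize = 1), fa = 2500,
                                energyTable = et, seed = 1)[[1]]
  consumed <- (hh$crop_records$produced_kg - hh$crop_records$sold_kg) * 3560
  sold_kcal <- hh$crop_records$sold_kg * hh$crop_records$price_per_kg / 1 * 3560
  nmae <- computeMae(hh$members)
  expect_equal((consumed + sold_kcal + 0) / (365 * nmae), 2500)

  # 200-household round trip through the full FA computation
  sc <- smallScene()
  fa <- computeFaTable(sc$households[1:200])
  expect_lt(max(abs(fa$FA - sc$targets$fa[1:200]) / sc$targets$fa[1:200]),
            0.001)
  expect_lt(max(abs(fa$banana - sc$targets$y[1:200])), 1e-6)

  # 50/50 crop vs off-farm split
  hh2 <- simulateSurveyResponses(loc, data.frame(maize = 0.5, offfarm = 0.5),
                                 fa = 2000, energyTable = et, seed = 2)
  con <- computeContributions(hh2[[1]], et)
  expect_equal(unname(con$activities[["crop"]]), 0.5, tolerance = 1e-9)
  expect_equal(unname(con$activities[["offfarm"]]), 0.5, tolerance = 1e-9)

  expect_error(simulateSurveyResponses(
    loc, data.frame(maize = 0.9), fa = 2000, energyTable = et),
    "sum to 1")
})

test_that("scene generation is deterministic and writes/reads round-trip", {
  s1 <- generateScene(nEa = 5, householdsPerEa = 2, extent = c(30, 31, 0, 1),
                      resolution = 0.1, seed = 9)
  s2 <- generateScene(nEa = 5, householdsPerEa = 2, extent = c(30, 31, 0, 1),
                      resolution = 0.1, seed = 9)
  expect_identical(s1$targets, s2$targets)
  expect_identical(gridValues(s1$covariates), gridValues(s2$covariates))
  # displacement bound between true and public locations
  d <- diag(famap:::geoDistKm(s1$trueLocations, s1$publicLocations))
  expect_true(all(d <= 10 + 1e-9))

  dir <- withr::local_tempdir()
  writeScene(s1, dir)
  hh <- readHouseholds(dir)
  expect_equal(length(hh), length(s1$households))
  fa1 <- computeFaTable(s1$households)
  fa2 <- computeFaTable(hh)
  expect_equal(fa2$FA, fa1$FA, tolerance = 1e-9)
  g <- readAsciiGrid(file.path(dir, "RAIN.asc"))
  expect_equal(g@values, s1$covariates@layers$RAIN@values, tolerance = 1e-7)
})
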