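# Synthetic survey scenes: covariate rasters plus LSMS-like households with
# known regression coefficients, inflation probabilities and residual
# spatial structure. The generator is the ground truth for every
# parameter-recovery test downstream.

#' Generate spatially structured covariate rasters
#'
#' Builds one raster layer per specification row on a common lon/lat grid.
#' Each layer is a stationary Gaussian random field with the requested
#' marginal mean and standard deviation and the requested practical
#' correlation range; `sd = 0` gives a constant layer.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in degrees (WGS84).
#' @param resolution cell size in degrees (> 0).
#' @param layerSpecs data.frame with columns `name`, `mean`, `sd`,
#'   `range_km`.
#' @param seed integer seed; identical seeds give identical stacks.
#' @return A [GridStack-class].
#' @export
generateCovariateRasters <- function(extent, resolution, layerSpecs, seed = 1) {
  stopIfNot(length(extent) == 4 && extent[2] > extent[1] && extent[4] > extent[3],
            "degenerate extent")
  stopIfNot(resolution > 0, "resolution must be > 0")
  stopIfNot(all(layerSpecs$range_km > 0), "spatial ranges must be > 0")
  nc <- max(1L, floor((extent[2] - extent[1]) / resolution + 1e-9))
  nr <- max(1L, floor((extent[4] - extent[3]) / resolution + 1e-9))
  template <- gridLayer("template", matrix(0, nr, nc), extent[1], extent[3],
                        resolution)
  cc <- cellCentres(template)
  layers <- lapply(seq_len(nrow(layerSpecs)), function(k) {
    sp <- layerSpecs[k, ]
    v <- if (sp$sd == 0) rep(0, nrow(cc)) else
      simulateGaussianField(cc, sp$range_km, seed = subSeed(seed, k))
    gridFromVector(template, sp$mean + sp$sd * v, name = sp$name)
  })
  gridStack(layers)
}

#' Generate clustered household locations by enumeration area
#'
#' Survey sampling emulation: enumeration-area (EA) centroids are uniform
#' over the extent and households scatter around their centroid with an
#' isotropic Gaussian spread. Households falling outside the extent are
#' rejection-resampled.
#'
#' @param nEa number of enumeration areas (>= 1).
#' @param householdsPerEa households per EA (>= 1).
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param clusterSdKm within-EA scatter (km); 0 collapses each EA onto its
#'   centroid.
#' @param seed integer seed.
#' @return data.frame with `ea`, `lon`, `lat`.
#' @export
generateEnumerationAreas <- function(nEa, householdsPerEa, extent,
                                     clusterSdKm = 2, seed = 1) {
  stopIfNot(nEa >= 1 && householdsPerEa >= 1, "counts must be >= 1")
  stopIfNot(extent[2] > extent[1] && extent[4] > extent[3], "degenerate extent")
  set.seed(seed)
  cx <- stats::runif(nEa, extent[1], extent[2])
  cy <- stats::runif(nEa, extent[3], extent[4])
  sd_lat <- clusterSdKm / 111.32
  out <- vector("list", nEa)
  for (e in seq_len(nEa)) {
    sd_lon <- sd_lat / max(cos(cy[e] * pi / 180), 0.1)
    lon <- lat <- numeric(householdsPerEa)
    for (i in seq_len(householdsPerEa)) {
      for (try in 1:1000) {
        x <- cx[e] + stats::rnorm(1, 0, sd_lon)
        y <- cy[e] + stats::rnorm(1, 0, sd_lat)
        if (x >= extent[1] && x <= extent[2] && y >= extent[3] && y <= extent[4])
          break
        if (try == 1000) stop("extent too small to place clusters", call. = FALSE)
      }
      lon[i] <- x; lat[i] <- y
    }
    out[[e]] <- data.frame(ea = e, lon = lon, lat = lat)
  }
  do.call(rbind, out)
}

#' Displace locations for privacy
#'
#' Moves every point a uniform random geodesic distance in `[0, maxOffsetKm]`
#' along a uniform random bearing, emulating the location displacement that
#' survey publishers apply (offsets up to 10 km).
#'
#' @param points data.frame with `lon`, `lat`.
#' @param maxOffsetKm maximum offset (km, >= 0).
#' @param seed integer seed.
#' @return data.frame with displaced `lon`, `lat` (other columns preserved).
#' @export
displaceForPrivacy <- function(points, maxOffsetKm = 10, seed = 1) {
  stopIfNot(maxOffsetKm >= 0, "maxOffsetKm must be >= 0")
  pts <- as.data.frame(points)
  if (maxOffsetKm == 0 || nrow(pts) == 0) return(pts)
  set.seed(seed)
  d <- stats::runif(nrow(pts), 0, maxOffsetKm)
  b <- stats::runif(nrow(pts), 0, 360)
  moved <- geoOffsetKm(pts[, c("lon", "lat")], d, b)
  pts$lon <- moved[, "lon"]
  pts$lat <- moved[, "lat"]
  pts
}

#' Ground-truth specification for a synthetic inflated-beta indicator
#'
#' Bundles the link-scale coefficients of the four distribution parameters,
#' the latent residual variogram, the log-FA trend model and the per-
#' parameter scaling of the shared latent residual field. Coefficient
#' vectors are named: `"(Intercept)"` plus covariate layer names.
#'
#' @param coefficients named list with elements `mu`, `sigma`, `nu`, `tau`,
#'   each a named numeric vector of link-scale coefficients.
#' @param residualVariogram a [VariogramModel-class] for the shared latent
#'   residual field (link scale).
#' @param residualScale named numeric: multiplier of the latent field on
#'   each parameter's predictor.
#' @param faModel list with `coefficients` (named, link = log) and
#'   `residualVariogram` for log-FA.
#' @param seed integer recorded for provenance.
#' @return object of class `SyntheticTruth`.
#' @export
syntheticTruth <- function(coefficients, residualVariogram,
                           residualScale = c(mu = 1, sigma = 0, nu = 0, tau = 0),
                           faModel = NULL, seed = NA_integer_) {
  stopIfNot(all(c("mu", "sigma", "nu", "tau") %in% names(coefficients)),
            "coefficients must cover mu, sigma, nu, tau")
  structure(list(coefficients = coefficients,
                 residualVariogram = residualVariogram,
                 residualScale = residualScale,
                 faModel = faModel, seed = seed),
            class = "SyntheticTruth")
}

# default truths: "signal" emulates a strongly environment-driven crop
# share (the highland-banana-like case); "noise" an ubiquitous crop whose
# share is spatially unstructured (pure-nugget residuals, no covariate
# effects)
#' @rdname syntheticTruth
#' @param kind `"signal"` or `"noise"`.
#' @export
defaultSyntheticTruth <- function(kind = c("signal", "noise")) {
  kind <- match.arg(kind)
  fa <- list(
    coefficients = c("(Intercept)" = log(2000), LGP = 0.25 / 40, SCARB = 0.15 / 8000),
    residualVariogram = variogramModel("matern", nugget = 0.30, sill = 0.42,
                                       range = 40, kappa = 0.5))
  if (kind == "signal") {
    syntheticTruth(
      coefficients = list(
        mu    = c("(Intercept)" = logit(0.35), RAIN = 1.5 / 300),
        sigma = c("(Intercept)" = logit(0.25)),
        nu    = c("(Intercept)" = log(0.35), RAIN = -1.5 / 300),
        tau   = c("(Intercept)" = log(0.05))),
      residualVariogram = variogramModel("matern", nugget = 0.10, sill = 1.10,
                                         range = 40, kappa = 0.5),
      residualScale = c(mu = 1, sigma = 0, nu = -1, tau = 0),
      faModel = fa)
  } else {
    syntheticTruth(
      coefficients = list(
        mu    = c("(Intercept)" = logit(0.30)),
        sigma = c("(Intercept)" = logit(0.40)),
        nu    = c("(Intercept)" = log(0.40)),
        tau   = c("(Intercept)" = log(0.05))),
      residualVariogram = variogramModel("matern", nugget = 0.85, sill = 0.85001,
                                         range = 40, kappa = 0.5),
      residualScale = c(mu = 1, sigma = 0, nu = 0, tau = 0),
      faModel = fa)
  }
}

#' @rdname generateScene
#' @export
defaultLayerSpecs <- function() {
  data.frame(name = c("RAIN", "LGP", "SCARB", "POP", "TRAV"),
             mean = c(1200, 200, 30000, 150, 120),
             sd = c(300, 40, 8000, 100, 60),
             range_km = c(250, 200, 150, 80, 100))
}

# latent residual field implied by a variogram model: spatially correlated
# component (partial sill) plus independent micro-scale noise (nugget)
latentResidualField <- function(points, vgm, seed) {
  n <- nrow(points)
  structured <- if (vgm@psill > 0)
    sqrt(vgm@psill) * simulateGaussianField(points, practicalRange(vgm),
                                            shape = vgm@shape, seed = seed)
  else rep(0, n)
  set.seed(subSeed(seed, 7919))
  structured + sqrt(vgm@nugget) * stats::rnorm(n)
}

#' Simulate a zero-and-one-inflated beta field at household locations
#'
#' Per location, the four distribution parameters are computed from
#' link-scale linear predictors of the sampled covariate values plus a
#' shared spatially correlated latent residual (scaled per parameter), and
#' one response is drawn from the mixed distribution: 0 with probability
#' P0, 1 with probability P1, else Beta(alpha, beta).
#'
#' @param locations data.frame with `lon`, `lat`.
#' @param covariates a [GridStack-class]; every covariate named in the
#'   truth's coefficients must be a layer.
#' @param truth a `SyntheticTruth`.
#' @param seed integer seed.
#' @return list with `y` (responses; `NA` for locations on nodata),
#'   `params` (data.frame of mu, sigma, nu, tau per location) and `valid`.
#' @export
simulateInflatedBetaField <- function(locations, covariates, truth, seed = 1) {
  covs <- sampleAtPoints(covariates, locations)
  need <- setdiff(unique(unlist(lapply(truth$coefficients, names))),
                  "(Intercept)")
  missing <- setdiff(need, layerNames(covariates))
  stopIfNot(length(missing) == 0,
            paste("coefficients reference missing covariates:",
                  paste(missing, collapse = ", ")))
  n <- nrow(covs)
  latent <- latentResidualField(locations, truth$residualVariogram,
                                subSeed(seed, 11))
  eta <- function(par) {
    cf <- truth$coefficients[[par]]
    v <- rep(cf[["(Intercept)"]], n)
    # covariates enter centred on their sample mean, so intercepts are the
    # link-scale value at average covariates; slopes are per raw unit
    for (nm in setdiff(names(cf), "(Intercept)"))
      v <- v + cf[[nm]] * (covs[[nm]] - mean(covs[[nm]], na.rm = TRUE))
    sc <- truth$residualScale[[par]]
    if (!is.null(sc) && !is.na(sc)) v <- v + sc * latent
    v
  }
  mu <- inv_logit(eta("mu")); sigma <- inv_logit(eta("sigma"))
  nu <- exp(eta("nu")); tau <- exp(eta("tau"))
  set.seed(subSeed(seed, 13))
  u <- stats::runif(n)
  p0 <- nu / (1 + nu + tau); p1 <- tau / (1 + nu + tau)
  sh <- beinfShape(pmin(pmax(mu, 1e-8), 1 - 1e-8),
                   pmin(pmax(sigma, 1e-8), 1 - 1e-8))
  y <- stats::rbeta(n, sh$alpha, sh$beta)
  y[u < p0] <- 0
  y[u >= p0 & u < p0 + p1] <- 1
  valid <- covs$valid
  y[!valid] <- NA
  if (any(!valid)) warning(sum(!valid), " location(s) on nodata excluded")
  list(y = y, params = data.frame(mu = mu, sigma = sigma, nu = nu, tau = tau),
       valid = valid)
}

#' Build survey records that reproduce target FA and contribution shares
#'
#' Inverts the food-availability computation: constructs household rosters,
#' production, sales and off-farm income such that recomputing FA and the
#' contribution shares from the records recovers the targets exactly (up to
#' floating-point rounding). Part of each product's share is routed through
#' sales (valued in staple-energy terms) so the records exercise both the
#' consumption and the income pathways.
#'
#' @param locations data.frame with `lon`, `lat` (one row per household).
#' @param shares data.frame, one column per product (plus optionally
#'   `offfarm`), rows summing to 1; products must exist in `energyTable`.
#' @param fa numeric target FA (kcal per male adult equivalent per day,
#'   > 0 wherever any share is > 0).
#' @param energyTable see [defaultEnergyTable()].
#' @param maeWeights see [defaultMaeWeights()].
#' @param seed integer seed (controls rosters, sold fractions, resources).
#' @return list of household records (see [computeFaTable()]).
#' @export
simulateSurveyResponses <- function(locations, shares, fa,
                                    energyTable = defaultEnergyTable(),
                                    maeWeights = defaultMaeWeights(),
                                    seed = 1) {
  locations <- as.data.frame(locations)
  shares <- as.data.frame(shares)
  n <- nrow(locations)
  stopIfNot(nrow(shares) == n && length(fa) == n,
            "locations, shares and fa must align")
  bad <- abs(rowSums(shares) - 1) > 1e-8
  stopIfNot(!any(bad), "shares must sum to 1 per household")
  stopIfNot(all(fa > 0), "target FA must be > 0")
  prods <- setdiff(names(shares), "offfarm")
  et <- energyTable$products
  missing <- setdiff(prods, et$product)
  stopIfNot(length(missing) == 0,
            paste("products not in energy table:", paste(missing, collapse = ", ")))
  infeasible <- prods[vapply(prods, function(p) {
    r <- et[et$product == p, ]
    any(shares[[p]] > 0) && r$energy_kcal_per_kg <= 0 && r$price_per_kg <= 0
  }, TRUE)]
  stopIfNot(length(infeasible) == 0,
            paste("infeasible targets (no energy, no price):",
                  paste(infeasible, collapse = ", ")))
  set.seed(seed)
  staple_e <- energyTable$staple_energy
  staple_p <- energyTable$staple_price
  records <- vector("list", n)
  for (i in seq_len(n)) {
    # roster: one reference adult male plus a random mix of members
    extra <- stats::rpois(1, 3)
    members <- data.frame(
      sex = c("male", sample(c("male", "female"), extra, replace = TRUE)),
      age = c(30, sample(c(2, 5, 9, 14, 25, 40, 65), extra, replace = TRUE)))
    n_mae <- computeMae(members, maeWeights)
    e_total <- fa[i] * 365 * n_mae
    crop <- live <- list()
    for (p in prods) {
      s <- shares[i, p]
      if (s <= 0) next
      r <- et[et$product == p, ]
      # non-food cash products (zero energy density) contribute via sales
      # only; otherwise a random part of production is sold
      f <- if (r$energy_kcal_per_kg <= 0) 1
           else if (r$price_per_kg > 0) stats::runif(1, 0, 0.5) else 0
      # energy per kg produced, combining consumed and sold pathways
      epk <- (1 - f) * r$energy_kcal_per_kg +
        f * r$price_per_kg / staple_p * staple_e
      produced <- s * e_total / epk
      rec <- data.frame(product = p, produced_kg = produced,
                        sold_kg = f * produced, price_per_kg = r$price_per_kg)
      if (r$activity == "livestock") live <- c(live, list(rec))
      else crop <- c(crop, list(rec))
    }
    off_s <- if ("offfarm" %in% names(shares)) shares[i, "offfarm"] else 0
    records[[i]] <- list(
      household_id = sprintf("hh%05d", i),
      lon = locations$lon[i], lat = locations$lat[i],
      members = members,
      crop_records = if (length(crop)) do.call(rbind, crop) else emptyProduction(),
      livestock_records = if (length(live)) do.call(rbind, live) else emptyProduction(),
      offfarm_income = off_s * e_total * staple_p / staple_e,
      land_area = stats::runif(1, 0.2, 5),
      herd_size = round(stats::runif(1, 0, 8), 1))
  }
  records
}

emptyProduction <- function()
  data.frame(product = character(), produced_kg = numeric(),
             sold_kg = numeric(), price_per_kg = numeric())

#' Generate a complete synthetic survey scene
#'
#' Draws covariate rasters, clustered household locations, a privacy-
#' displaced copy of the locations, one covariate-driven (or pure-noise)
#' inflated-beta contribution indicator, a lognormal FA field, and survey
#' records whose recomputed FA and shares reproduce the simulated targets.
#' The primary indicator is labelled `"banana"`; the remainder of each
#' household's share budget is split between a generic crop and off-farm
#' income.
#'
#' @param nEa,householdsPerEa sampling design (defaults give 1000
#'   households, the scale of the retained national survey emulated here).
#' @param extent,resolution grid specification (defaults: a 4 x 4 degree
#'   window at 5 arc minutes).
#' @param layerSpecs covariate specifications, see [defaultLayerSpecs()].
#' @param truth a `SyntheticTruth` for the primary indicator.
#' @param clusterSdKm within-EA scatter.
#' @param displacementKm privacy displacement bound (10 km as published
#'   surveys apply).
#' @param seed integer master seed; all sub-seeds derive from it.
#' @return object of class `SyntheticScene`: list with `covariates`,
#'   `households`, `trueLocations`, `publicLocations`, `truth`, `targets`
#'   (data.frame with `fa` and `y`), `indicator`.
#' @export
generateScene <- function(nEa = 100, householdsPerEa = 10,
                          extent = c(30, 34, -1, 3), resolution = 5 / 60,
                          layerSpecs = defaultLayerSpecs(),
                          truth = defaultSyntheticTruth("signal"),
                          clusterSdKm = 2, displacementKm = 10, seed = 1) {
  covariates <- generateCovariateRasters(extent, resolution, layerSpecs,
                                         seed = subSeed(seed, 1))
  locs <- generateEnumerationAreas(nEa, householdsPerEa, extent, clusterSdKm,
                                   seed = subSeed(seed, 2))
  public <- displaceForPrivacy(locs, displacementKm, seed = subSeed(seed, 3))
  # responses are generated at the true locations; the analysis only ever
  # sees the displaced ones, as with published survey data
  sim <- simulateInflatedBetaField(locs, covariates, truth,
                                   seed = subSeed(seed, 4))
  y <- sim$y
  covs <- sampleAtPoints(covariates, locs)
  fa_cf <- truth$faModel$coefficients
  eta <- rep(fa_cf[["(Intercept)"]], nrow(locs))
  for (nm in setdiff(names(fa_cf), "(Intercept)"))
    eta <- eta + fa_cf[[nm]] * (covs[[nm]] - mean(covs[[nm]], na.rm = TRUE))
  eta <- eta + latentResidualField(locs, truth$faModel$residualVariogram,
                                   subSeed(seed, 5))
  fa <- exp(eta)
  set.seed(subSeed(seed, 6))
  u <- stats::runif(nrow(locs), 0.3, 0.7)
  shares <- data.frame(banana = y,
                       other_crop = (1 - y) * u,
                       offfarm = (1 - y) * (1 - u))
  households <- simulateSurveyResponses(locs, shares, fa,
                                        seed = subSeed(seed, 8))
  for (i in seq_along(households)) {    # analysis coordinates = public ones
    households[[i]]$lon <- public$lon[i]
    households[[i]]$lat <- public$lat[i]
  }
  structure(list(covariates = covariates, households = households,
                 trueLocations = locs[, c("lon", "lat")],
                 publicLocations = public[, c("lon", "lat")],
                 truth = truth, targets = data.frame(fa = fa, y = y),
                 indicator = "banana", seed = seed),
            class = "SyntheticScene")
}

#' Write a synthetic scene to disk
#'
#' Writes the household tables (parent plus roster and production child
#' tables keyed by household id) as CSV, the covariate stack as ESRI ASCII
#' grids, and the truth ledger as JSON.
#'
#' @param scene a `SyntheticScene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeHouseholds(scene$households, dir)
  for (nm in layerNames(scene$covariates))
    writeAsciiGrid(scene$covariates@layers[[nm]],
                   file.path(dir, paste0(nm, ".asc")))
  truth <- scene$truth
  truth$residualVariogram <- variogramAsList(truth$residualVariogram)
  if (!is.null(truth$faModel))
    truth$faModel$residualVariogram <-
      variogramAsList(truth$faModel$residualVariogram)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

variogramAsList <- function(m)
  list(shape = m@shape, nugget = m@nugget, sill = m@nugget + m@psill,
       range = m@range, kappa = m@kappa)

#' Read / write household survey tables
#'
#' The on-disk format is a parent `households.csv` plus child tables
#' `members.csv` and `production.csv` keyed by `household_id`.
#'
#' @param households list of household records.
#' @param dir directory.
#' @return `readHouseholds` returns a list of household records.
#' @export
writeHouseholds <- function(households, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parent <- do.call(rbind, lapply(households, function(h)
    data.frame(household_id = h$household_id, lon = h$lon, lat = h$lat,
               offfarm_income = h$offfarm_income, land_area = h$land_area,
               herd_size = h$herd_size)))
  members <- do.call(rbind, lapply(households, function(h)
    if (nrow(h$members)) cbind(household_id = h$household_id, h$members)))
  prod <- do.call(rbind, lapply(households, function(h) {
    rbind(
      if (nrow(h$crop_records))
        cbind(household_id = h$household_id, type = "crop", h$crop_records),
      if (nrow(h$livestock_records))
        cbind(household_id = h$household_id, type = "livestock",
              h$livestock_records))
  }))
  utils::write.csv(parent, file.path(dir, "households.csv"), row.names = FALSE)
  utils::write.csv(members, file.path(dir, "members.csv"), row.names = FALSE)
  utils::write.csv(prod, file.path(dir, "production.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeHouseholds
#' @export
readHouseholds <- function(dir) {
  parent <- utils::read.csv(file.path(dir, "households.csv"))
  members <- utils::read.csv(file.path(dir, "members.csv"))
  prod <- utils::read.csv(file.path(dir, "production.csv"))
  lapply(seq_len(nrow(parent)), function(i) {
    id <- parent$household_id[i]
    pr <- prod[prod$household_id == id, ]
    list(household_id = id, lon = parent$lon[i], lat = parent$lat[i],
         members = members[members$household_id == id, c("sex", "age")],
         crop_records = pr[pr$type == "crop",
                           c("product", "produced_kg", "sold_kg", "price_per_kg")],
         livestock_records = pr[pr$type == "livestock",
                                c("product", "produced_kg", "sold_kg", "price_per_kg")],
         offfarm_income = parent$offfarm_income[i],
         land_area = parent$land_area[i], herd_size = parent$herd_size[i])
  })
}
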