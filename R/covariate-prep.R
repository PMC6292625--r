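# Point-level covariate preparation: jittering clustered locations for
# kriging (which needs unique points) and soil carbon stock computation.
# Raster resampling and point sampling live in grid.R.

#' Jitter coincident locations to make all points unique
#'
#' Published survey locations cluster several households on identical
#' coordinates; kriging requires unique points. Every point is moved by a
#' uniform random distance up to `maxOffsetM` along a uniform random
#' bearing; residual collisions are re-jittered until all points are
#' pairwise distinct (bounded retries).
#'
#' @param points data.frame with `lon`, `lat`.
#' @param maxOffsetM maximum offset in metres (default 50).
#' @param seed integer seed.
#' @return data.frame with unique `lon`, `lat` (other columns preserved).
#' @export
jitterDuplicates <- function(points, maxOffsetM = 50, seed = 1) {
  pts <- as.data.frame(points)
  if (nrow(pts) == 0) return(pts)
  key <- function(p) paste(sprintf("%.12f", p$lon), sprintf("%.12f", p$lat))
  if (maxOffsetM == 0) {
    stopIfNot(!anyDuplicated(key(pts)),
              "maxOffsetM = 0 but input contains coincident points")
    return(pts)
  }
  set.seed(seed)
  out <- pts
  todo <- rep(TRUE, nrow(pts))            # first pass jitters every point
  for (round in 1:100) {
    n <- sum(todo)
    if (n == 0) break
    d <- stats::runif(n, 0, maxOffsetM / 1000)
    b <- stats::runif(n, 0, 360)
    moved <- geoOffsetKm(pts[todo, c("lon", "lat")], d, b)
    out$lon[todo] <- moved[, "lon"]
    out$lat[todo] <- moved[, "lat"]
    todo <- duplicated(key(out))          # re-draw residual collisions only
  }
  stopIfNot(!anyDuplicated(key(out)), "could not resolve coincident points")
  out
}

#' Soil carbon stock from bulk density and carbon content
#'
#' Per soil layer, `SCARB_i = BD_i * dz_i * SOC_i * 1e4`, for the three
#' standard layers 0-0.05, 0.05-0.15 and 0.15-0.30 m; the mean across the
#' three layers is the covariate used downstream. The formula is applied
#' literally with the 1e4 factor; note that dimensionally it yields a mass
#' of carbon per unit area per layer rather than a concentration.
#'
#' @param bd bulk density per layer (Mg m^-3), length 3, > 0.
#' @param soc soil organic carbon content per layer (kg C Mg^-1), length 3.
#' @param dz layer thicknesses in m (default `c(0.05, 0.10, 0.15)`).
#' @return list with `per_layer` (length 3) and `mean`.
#' @export
computeScarb <- function(bd, soc, dz = c(0.05, 0.10, 0.15)) {
  stopIfNot(length(bd) == 3 && length(soc) == 3 && length(dz) == 3,
            "three soil layers are required")
  stopIfNot(all(bd > 0) && all(dz > 0), "BD and dz must be > 0")
  per <- bd * dz * soc * 1e4
  list(per_layer = per, mean = mean(per))
}
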