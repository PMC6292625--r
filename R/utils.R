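# internal helpers shared across modules

logit <- function(p) log(p / (1 - p))

#' @importFrom stats plogis
inv_logit <- function(x) plogis(x)

# Geodesic distance matrix in km between two sets of lon/lat points
# (two-column matrices), on the WGS84 ellipsoid. The analysis keeps
# geographic coordinates throughout and never projects.
geoDistKm <- function(p1, p2 = NULL) {
  p1 <- as.matrix(p1)[, 1:2, drop = FALSE]
  if (is.null(p2)) {
    geosphere::distm(p1, fun = geosphere::distGeo) / 1000
  } else {
    p2 <- as.matrix(p2)[, 1:2, drop = FALSE]
    geosphere::distm(p1, p2, fun = geosphere::distGeo) / 1000
  }
}

# Displace lon/lat points by a distance (km) along a bearing (degrees).
geoOffsetKm <- function(points, distance_km, bearing_deg) {
  out <- geosphere::destPoint(as.matrix(points)[, 1:2, drop = FALSE],
                              b = bearing_deg, d = distance_km * 1000)
  colnames(out) <- c("lon", "lat")
  out
}

# Derive a module-level sub-seed from the scene seed; keeps every seed
# a valid 32-bit integer.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
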