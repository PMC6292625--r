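# shared fixtures, built in code

# tiny constant-free covariate stack on a small grid
makeTestStack <- function(seed = 11, extent = c(30, 31, 0, 1), res = 0.1) {
  generateCovariateRasters(
    extent, res,
    data.frame(name = c("RAIN", "LGP"), mean = c(1200, 200),
               sd = c(300, 40), range_km = c(60, 50)), seed = seed)
}

# energy table with unit staple price for hand arithmetic
unitEnergyTable <- function() {
  list(products = data.frame(
    product = c("maize", "banana", "cattle"),
    activity = c("crop", "crop", "livestock"),
    energy_kcal_per_kg = c(3560, 890, 1500),
    price_per_kg = c(1, 2, 10)),
    staple = "maize", staple_energy = 3560, staple_price = 1)
}

makeHousehold <- function(id = "hh1", lon = 30, lat = 0,
                          members = data.frame(sex = "male", age = 30),
                          crop = NULL, livestock = NULL,
                          offfarm = 0, land = 1, herd = 0) {
  empty <- data.frame(product = character(), produced_kg = numeric(),
                      sold_kg = numeric(), price_per_kg = numeric())
  list(household_id = id, lon = lon, lat = lat, members = members,
       crop_records = if (is.null(crop)) empty else crop,
       livestock_records = if (is.null(livestock)) empty else livestock,
       offfarm_income = offfarm, land_area = land, herd_size = herd)
}

# small shared scene, generated once per test run
sceneCache <- new.env()
smallScene <- function() {
  if (is.null(sceneCache$scene))
    sceneCache$scene <- generateScene(nEa = 40, householdsPerEa = 5,
                                      extent = c(30, 32, 0, 2),
                                      resolution = 1 / 6, seed = 101)
  sceneCache$scene
}
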