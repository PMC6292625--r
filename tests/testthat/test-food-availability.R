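test_that("male-adult-equivalent standardisation follows the weight table", {
  m1 <- data.frame(sex = "male", age = 30)
  expect_equal(computeMae(m1), 1.0)
  expect_equal(computeMae(rbind(m1, m1)), 2.0)
  # adult male plus adult female (weight 0.76 in the shipped table)
  expect_equal(computeMae(data.frame(sex = c("male", "female"),
                                     age = c(30, 28))), 1.76)
  expect_error(computeMae(data.frame(sex = "male", age = 150)),
               "no MAE weight band")
  expect_equal(computeMae(data.frame(sex = character(), age = numeric())), 0)
})

test_that("consumed energy is produced-minus-sold times energy density", {
  et <- unitEnergyTable()
  crop <- data.frame(product = "maize", produced_kg = 1000, sold_kg = 400,
                     price_per_kg = 1)
  none <- crop[0, ]
  expect_equal(computeEnergyConsumed(crop, none, et), 600 * 3560)
  allSold <- transform(crop, sold_kg = produced_kg)
  expect_equal(computeEnergyConsumed(allSold, none, et), 0)
  expect_equal(computeEnergyConsumed(none, none, et), 0)
  expect_error(computeEnergyConsumed(
    data.frame(product = "yam", produced_kg = 1, sold_kg = 0,
               price_per_kg = 0), none, et), "missing from energy table")
  # sold > produced is clipped with a warning, or errors in strict mode
  over <- data.frame(product = "maize", produced_kg = 10, sold_kg = 20,
                     price_per_kg = 1)
  expect_warning(v <- computeEnergyConsumed(over, none, et), "clipped")
  expect_equal(v, 0)
  expect_error(computeEnergyConsumed(over, none, et, strict = TRUE), "exceeds")
})

test_that("income energy converts currency through the staple", {
  et <- unitEnergyTable()   # staple price 1, energy 3560
  none <- et$products[0, c("product")] |>
    cbind(produced_kg = numeric(), sold_kg = numeric(),
          price_per_kg = numeric())
  expect_equal(computeEnergyIncome(none, none, 100, et), 356000)
  expect_equal(computeEnergyIncome(none, none, 0, et), 0)
  et2 <- et; et2$staple_price <- 2
  expect_equal(computeEnergyIncome(none, none, 100, et2), 356000 / 2)
})

test_that("the FA identity holds", {
  expect_equal(computeFa(912500, 0, 1)$FA, 2500)
  expect_equal(computeFa(0, 0, 2)$FA, 0)
  expect_equal(computeFa(500000, 230000, 2)$FA, 1000)
  expect_error(computeFa(1, 1, 0), "n_hh_mae")
  # identity FA * 365 * n_mae = E_consumed + E_income on random inputs
  set.seed(1)
  for (i in 1:20) {
    ec <- runif(1, 0, 1e6); ei <- runif(1, 0, 1e6); nm <- runif(1, 0.5, 10)
    fa <- computeFa(ec, ei, nm)
    expect_equal(fa$FA * 365 * nm, ec + ei, tolerance = 1e-9)
  }
})

test_that("contribution shares respect the category hierarchy", {
  et <- unitEnergyTable()
  offOnly <- makeHousehold(offfarm = 1000)
  con <- computeContributions(offOnly, et)
  expect_equal(unname(con$activities), c(0, 0, 1))

  banOnly <- makeHousehold(crop = data.frame(
    product = "banana", produced_kg = 100, sold_kg = 0, price_per_kg = 2))
  con <- computeContributions(banOnly, et)
  expect_equal(unname(con$activities[["crop"]]), 1)
  expect_equal(unname(con$products[["banana"]]), 1)

  # two equal energy sources: maize consumed vs cattle sales
  maizeE <- 1000 * 3560
  cattleSold <- maizeE / (10 / 1 * 3560)   # kg so that income energy matches
  two <- makeHousehold(
    crop = data.frame(product = "maize", produced_kg = 1000, sold_kg = 0,
                      price_per_kg = 1),
    livestock = data.frame(product = "cattle", produced_kg = cattleSold,
                           sold_kg = cattleSold, price_per_kg = 10))
  con <- computeContributions(two, et)
  expect_equal(unname(con$activities), c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(unname(con$products[["maize"]]), 0.5, tolerance = 1e-12)
  expect_equal(unname(con$products[["cattle"]]), 0.5, tolerance = 1e-12)

  # zero FA: flagged, all-zero
  con0 <- computeContributions(makeHousehold(), et)
  expect_false(con0$defined)
  expect_true(all(con0$activities == 0))
})

test_that("share normalisation and scale equivariance hold on a scene", {
  sc <- smallScene()
  fa <- computeFaTable(sc$households[1:50])
  act <- fa$crop + fa$livestock + fa$offfarm
  expect_equal(act, rep(1, 50), tolerance = 1e-9)
  prodCols <- intersect(names(fa), defaultEnergyTable()$products$product)
  cropSum <- rowSums(fa[, intersect(prodCols, c("banana", "sorghum", "maize",
                                                "cassava", "beans", "coffee",
                                                "other_crop")), drop = FALSE])
  expect_equal(cropSum, fa$crop, tolerance = 1e-9)

  # scaling all quantities and incomes by c scales FA, leaves shares alone
  h <- sc$households[[1]]
  h2 <- h
  h2$crop_records$produced_kg <- h$crop_records$produced_kg * 3
  h2$crop_records$sold_kg <- h$crop_records$sold_kg * 3
  h2$livestock_records$produced_kg <- h$livestock_records$produced_kg * 3
  h2$livestock_records$sold_kg <- h$livestock_records$sold_kg * 3
  h2$offfarm_income <- h$offfarm_income * 3
  t1 <- computeFaTable(list(h)); t2 <- computeFaTable(list(h2))
  expect_equal(t2$FA, 3 * t1$FA, tolerance = 1e-9)
  expect_equal(t2$banana, t1$banana, tolerance = 1e-9)
  expect_equal(t2$offfarm, t1$offfarm, tolerance = 1e-9)
})

test_that("household filters retain land-holding, active households", {
  hhs <- list(
    makeHousehold("a", land = 0, offfarm = 10),
    makeHousehold("b", land = 0),
    makeHousehold("c", land = 1, offfarm = 10),
    makeHousehold("d", land = 1),     # land but no activity
    makeHousehold("e", land = 2, crop = data.frame(
      product = "maize", produced_kg = 10, sold_kg = 0, price_per_kg = 1)))
  f <- filterHouseholds(hhs)
  expect_equal(vapply(f$retained, `[[`, "", "household_id"), c("c", "e"))
  expect_setequal(f$exclusions$household_id, c("a", "b", "d"))
  expect_equal(f$exclusions$reason[f$exclusions$household_id == "d"],
               "no livelihood activities")
  allGood <- hhs[c(3, 5)]
  expect_equal(length(filterHouseholds(allGood)$retained), 2)
})
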