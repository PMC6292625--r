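# Household food-availability (FA) indicator and contribution shares.
#
# FA is the potential daily food energy available per male adult equivalent
# (kcal cap^-1 d^-1): energy from consumed own production plus all income
# (product sales and off-farm) converted to staple-food energy, divided by
# 365 days and the household size in male adult equivalents.

#' Default energy conversion and price table
#'
#' Product-level energy densities (kcal/kg) and farm-gate prices, with maize
#' as the staple food whose price and energy density convert income to
#' energy terms. The shipped values are editable placeholders of realistic
#' magnitude, not copies of any published product database; replace the CSV
#' (or pass `path`) to use study-specific values.
#'
#' @param path CSV with columns `product`, `activity`, `energy_kcal_per_kg`,
#'   `price_per_kg`.
#' @param staple staple product name (must be in the table).
#' @return list with `products` (data.frame), `staple`, `staple_energy`,
#'   `staple_price`.
#' @export
defaultEnergyTable <- function(path = system.file("extdata", "energy_table.csv",
                                                  package = "famap"),
                               staple = "maize") {
  products <- utils::read.csv(path)
  stopIfNot(staple %in% products$product, "staple must be present in table")
  srow <- products[products$product == staple, ]
  stopIfNot(srow$price_per_kg > 0, "staple price must be > 0")
  stopIfNot(srow$energy_kcal_per_kg > 0, "staple energy density must be > 0")
  list(products = products, staple = staple,
       staple_energy = srow$energy_kcal_per_kg,
       staple_price = srow$price_per_kg)
}

#' Default male-adult-equivalent weight table
#'
#' Sex- and age-band energy requirements relative to an adult male
#' (2500 kcal cap^-1 d^-1, weight 1). The shipped bands are a documented
#' default; correctness of the MAE standardisation is defined relative to
#' the configured table, which can be replaced via `path`.
#'
#' @param path CSV with columns `sex` (`male`/`female`/`any`), `age_min`,
#'   `age_max`, `weight`.
#' @return list with `table` (data.frame) and `reference_energy` (2500).
#' @export
defaultMaeWeights <- function(path = system.file("extdata", "mae_weights.csv",
                                                 package = "famap")) {
  tab <- utils::read.csv(path)
  stopIfNot(all(tab$weight > 0 & tab$weight <= 1.5),
            "weights must be in (0, 1.5]")
  list(table = tab, reference_energy = 2500)
}

#' Household size in male adult equivalents
#'
#' Sums, over household members, the energy-requirement weight of the
#' member's sex and age band.
#'
#' @param members data.frame with `sex` and `age` (years).
#' @param weights see [defaultMaeWeights()].
#' @return numeric `n_hh_mae` (> 0 for non-empty rosters).
#' @export
computeMae <- function(members, weights = defaultMaeWeights()) {
  if (nrow(members) == 0) return(0)
  tab <- weights$table
  w <- vapply(seq_len(nrow(members)), function(i) {
    hit <- tab[(tab$sex == members$sex[i] | tab$sex == "any") &
                 tab$age_min <= members$age[i] & members$age[i] <= tab$age_max, ]
    if (nrow(hit) == 0)
      stop("no MAE weight band for member ", i, " (", members$sex[i], ", age ",
           members$age[i], ")", call. = FALSE)
    hit$weight[1]
  }, 0)
  sum(w)
}

lookupEnergy <- function(products, energyTable) {
  idx <- match(products, energyTable$products$product)
  if (anyNA(idx))
    stop("product(s) missing from energy table: ",
         paste(products[is.na(idx)], collapse = ", "), call. = FALSE)
  energyTable$products$energy_kcal_per_kg[idx]
}

# clip sold > produced (survey noise) unless strict
cleanRecords <- function(records, strict = FALSE) {
  if (nrow(records) == 0) return(records)
  over <- records$sold_kg > records$produced_kg + 1e-12
  if (any(over)) {
    if (strict) stop("sold quantity exceeds produced quantity", call. = FALSE)
    warning("sold > produced for ", sum(over), " record(s); clipped to produced")
    records$sold_kg[over] <- records$produced_kg[over]
  }
  records
}

#' Annual energy from consumed own production
#'
#' Consumption is the difference between produced and sold quantities of
#' every crop and livestock product, valued at the product's energy density.
#'
#' @param cropRecords,livestockRecords data.frames with `product`,
#'   `produced_kg`, `sold_kg`.
#' @param energyTable see [defaultEnergyTable()].
#' @param strict error (instead of clip-with-warning) when sold > produced.
#' @return E_consumed in kcal/yr (>= 0).
#' @export
computeEnergyConsumed <- function(cropRecords, livestockRecords,
                                  energyTable = defaultEnergyTable(),
                                  strict = FALSE) {
  recs <- rbind(cleanRecords(cropRecords, strict),
                cleanRecords(livestockRecords, strict))
  if (nrow(recs) == 0) return(0)
  sum((recs$produced_kg - recs$sold_kg) * lookupEnergy(recs$product, energyTable))
}

#' Annual energy purchasable from income
#'
#' All income (product sales at their unit prices plus off-farm income) is
#' assumed to purchase the staple food; the staple price and energy density
#' convert currency to kcal/yr.
#'
#' @inheritParams computeEnergyConsumed
#' @param offfarmIncome currency/yr.
#' @return E_income in kcal/yr.
#' @export
computeEnergyIncome <- function(cropRecords, livestockRecords, offfarmIncome,
                                energyTable = defaultEnergyTable()) {
  stopIfNot(energyTable$staple_price > 0, "staple price must be > 0")
  recs <- rbind(cropRecords, livestockRecords)
  sales <- if (nrow(recs) == 0) 0 else sum(recs$sold_kg * recs$price_per_kg)
  (sales + offfarmIncome) / energyTable$staple_price * energyTable$staple_energy
}

#' Food availability indicator
#'
#' `FA = (E_consumed + E_income) / (365 * n_hh_mae)`, in kcal per male adult
#' equivalent per day.
#'
#' @param eConsumed,eIncome annual energies (kcal/yr).
#' @param nMae household size in male adult equivalents (> 0).
#' @return list with `FA`, `E_consumed`, `E_income`, `n_hh_mae`.
#' @export
computeFa <- function(eConsumed, eIncome, nMae) {
  stopIfNot(nMae > 0, "n_hh_mae must be > 0")
  list(FA = (eConsumed + eIncome) / (365 * nMae),
       E_consumed = eConsumed, E_income = eIncome, n_hh_mae = nMae)
}

#' Relative contributions of livelihood activities to FA
#'
#' Attributes each product's consumed energy plus its sales income (in
#' staple-energy terms) to the product and to the product's activity (crop
#' or livestock); off-farm income is its own activity. Shares are energies
#' divided by total energy, so activity shares sum to 1 and product-level
#' shares sum to their activity's share. A household with zero FA gets
#' all-zero shares and `defined = FALSE`.
#'
#' @param record household record (list with `crop_records`,
#'   `livestock_records`, `offfarm_income`).
#' @param energyTable see [defaultEnergyTable()].
#' @param strict see [computeEnergyConsumed()].
#' @return list with `activities` (crop, livestock, offfarm), `products`
#'   (named share per product present in the energy table) and `defined`.
#' @export
computeContributions <- function(record, energyTable = defaultEnergyTable(),
                                 strict = FALSE) {
  et <- energyTable$products
  recs <- rbind(cbind(cleanRecords(record$crop_records, strict)),
                cbind(cleanRecords(record$livestock_records, strict)))
  prodE <- stats::setNames(rep(0, nrow(et)), et$product)
  if (nrow(recs) > 0) {
    e <- (recs$produced_kg - recs$sold_kg) * lookupEnergy(recs$product, energyTable) +
      recs$sold_kg * recs$price_per_kg / energyTable$staple_price *
        energyTable$staple_energy
    agg <- tapply(e, recs$product, sum)
    prodE[names(agg)] <- agg
  }
  offE <- record$offfarm_income / energyTable$staple_price * energyTable$staple_energy
  total <- sum(prodE) + offE
  if (total <= 0)
    return(list(activities = c(crop = 0, livestock = 0, offfarm = 0),
                products = prodE, defined = FALSE))
  pshare <- prodE / total
  act <- c(crop = sum(pshare[et$product[et$activity == "crop"]]),
           livestock = sum(pshare[et$product[et$activity == "livestock"]]),
           offfarm = offE / total)
  list(activities = act, products = pshare, defined = TRUE)
}

#' Apply the study's household inclusion filters
#'
#' Retains households with land holdings (`land_area > 0`) and at least one
#' livelihood activity (any production record or off-farm income). Every
#' exclusion is logged with its reason.
#'
#' @param households list of household records.
#' @return list with `retained` (household list) and `exclusions`
#'   (data.frame with `household_id`, `reason`).
#' @export
filterHouseholds <- function(households) {
  reasons <- vapply(households, function(h) {
    if (is.na(h$land_area) || h$land_area <= 0) return("no land holdings")
    active <- nrow(h$crop_records) > 0 || nrow(h$livestock_records) > 0 ||
      (!is.na(h$offfarm_income) && h$offfarm_income > 0)
    if (!active) return("no livelihood activities")
    ""
  }, "")
  keep <- reasons == ""
  list(retained = households[keep],
       exclusions = data.frame(
         household_id = vapply(households[!keep], `[[`, "", "household_id"),
         reason = reasons[!keep]))
}

#' Per-household FA and contribution table
#'
#' Convenience wrapper running the complete indicator computation for a list
#' of household records.
#'
#' @param households list of household records.
#' @param energyTable,maeWeights configuration tables.
#' @param strict see [computeEnergyConsumed()].
#' @return data.frame with `household_id`, `lon`, `lat`, `FA`, activity
#'   shares (`crop`, `livestock`, `offfarm`), one column per product share,
#'   and household resource covariates (`land_area`, `herd_size`,
#'   `hh_size`).
#' @export
computeFaTable <- function(households, energyTable = defaultEnergyTable(),
                           maeWeights = defaultMaeWeights(), strict = FALSE) {
  rows <- lapply(households, function(h) {
    nmae <- computeMae(h$members, maeWeights)
    ec <- computeEnergyConsumed(h$crop_records, h$livestock_records,
                                energyTable, strict)
    ei <- computeEnergyIncome(h$crop_records, h$livestock_records,
                              h$offfarm_income, energyTable)
    fa <- computeFa(ec, ei, nmae)
    con <- computeContributions(h, energyTable, strict)
    cbind(data.frame(household_id = h$household_id, lon = h$lon, lat = h$lat,
                     FA = fa$FA),
          as.data.frame(as.list(con$activities)),
          as.data.frame(as.list(con$products)),
          data.frame(land_area = h$land_area, herd_size = h$herd_size,
                     hh_size = nrow(h$members)))
  })
  do.call(rbind, rows)
}
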