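# Fixture builders and independent oracles used across the suite.

make_record <- function(upc = "93000000000017", name = "Test product",
                        category_id = "bread", is_beverage = NA,
                        serving_size_g = NA_real_, energy_kj = 500,
                        protein_g = 5, total_fat_g = 2,
                        saturated_fat_g = 0.5, carbohydrate_g = 30,
                        sugars_g = 4, sodium_mg = 100, fiber_g = 3,
                        calcium_mg = NA_real_,
                        pct_fvnl_nonconc = NA_real_,
                        pct_fvnl_conc = NA_real_,
                        pct_non_fvnl = NA_real_,
                        provenance = "surveyed") {
  tibble::tibble(
    upc = upc, name = name, brand = "Acme", category_id = category_id,
    is_beverage = is_beverage, serving_size_g = serving_size_g,
    energy_kj = energy_kj, protein_g = protein_g,
    total_fat_g = total_fat_g, saturated_fat_g = saturated_fat_g,
    carbohydrate_g = carbohydrate_g, sugars_g = sugars_g,
    sodium_mg = sodium_mg, fiber_g = fiber_g, calcium_mg = calcium_mg,
    pct_fvnl_nonconc = pct_fvnl_nonconc, pct_fvnl_conc = pct_fvnl_conc,
    pct_non_fvnl = pct_non_fvnl, provenance = provenance
  )
}

make_categories <- function() {
  tibble::tibble(
    category_id = c("bread", "cheese", "oils", "softdrink", "juice", "eggs"),
    name = c("Bread", "Cheese", "Edible oils", "Sugar-sweetened soft drinks",
             "Fruit juice", "Eggs"),
    is_beverage = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    fiber_possible = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    fvnl_possible = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    default_fvnl_pct = c(NA, NA, NA, NA, 95, NA),
    npsc_category3_member = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    is_cheese = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    switch_excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    standard_message = c(NA, NA, NA,
                         "Sugar-free drinks and water are healthier choices",
                         NA, NA)
  )
}

# small hand-built database covering all scoring categories and rules
tiny_db <- function() {
  recs <- dplyr::bind_rows(
    make_record("00000001", "White bread", "bread", sodium_mg = 450,
                fiber_g = 2.5),
    make_record("00000018", "Grain bread", "bread", sodium_mg = 380,
                fiber_g = NA_real_),
    make_record("00000025", "Cheddar", "cheese", energy_kj = 1600,
                protein_g = 25, total_fat_g = 33, saturated_fat_g = 21,
                carbohydrate_g = 1, sugars_g = 0.5, sodium_mg = 650,
                fiber_g = NA_real_, calcium_mg = 720),
    make_record("00000032", "Soft cheese", "cheese", energy_kj = 1200,
                protein_g = 9, total_fat_g = 26, saturated_fat_g = 17,
                carbohydrate_g = 3, sugars_g = 3, sodium_mg = 350,
                fiber_g = NA_real_, calcium_mg = NA_real_),
    make_record("00000049", "Olive oil", "oils", energy_kj = 3400,
                protein_g = 0, total_fat_g = 91, saturated_fat_g = 14,
                carbohydrate_g = 0, sugars_g = 0, sodium_mg = 0,
                fiber_g = NA_real_),
    make_record("00000056", "Cola", "softdrink", energy_kj = 180,
                protein_g = 0, total_fat_g = 0, saturated_fat_g = 0,
                carbohydrate_g = 11, sugars_g = 10.6, sodium_mg = 10,
                fiber_g = NA_real_),
    make_record("00000063", "Orange juice", "juice", energy_kj = 170,
                protein_g = 0.6, total_fat_g = 0.1, saturated_fat_g = 0,
                carbohydrate_g = 9, sugars_g = 8.5, sodium_mg = 3,
                fiber_g = NA_real_, pct_fvnl_nonconc = 98,
                pct_fvnl_conc = 0, pct_non_fvnl = 2),
    make_record("00000070", "Eggs dozen", "eggs", energy_kj = 580,
                protein_g = 12.5, total_fat_g = 10, saturated_fat_g = 3.3,
                carbohydrate_g = 1, sugars_g = 0.5, sodium_mg = 140,
                fiber_g = NA_real_)
  )
  suppressWarnings(food_database(recs, make_categories()))
}

# Independent point-lookup oracle: walks the raw step table one threshold
# at a time instead of using the package's counting shortcut.
oracle_step_points <- function(value, steps) {
  pts <- 0L
  for (s in steps) {
    if (value > s) pts <- pts + 1L else break
  }
  pts
}

oracle_v_points <- function(pct) {
  if (pct >= 100) 8L
  else if (pct > 80) 5L
  else if (pct > 60) 2L
  else if (pct > 40) 1L
  else 0L
}

# brute-force healthier-switch oracle: filter same category, strictly
# better key, sort with the documented tie-breaks, truncate
oracle_recommend <- function(db, upc, mode = "npsc", max_results = 10L) {
  recs <- dplyr::left_join(db$records,
                           db$scores[, c("upc", "final_score")], by = "upc")
  q <- recs[recs$upc == upc, ]
  cat_row <- db$categories[db$categories$category_id == q$category_id, ]
  if (isTRUE(cat_row$switch_excluded)) {
    return(list(upcs = character(), message = cat_row$standard_message))
  }
  pool <- recs[recs$category_id == q$category_id & recs$upc != upc, ]
  if (mode == "npsc") {
    pool <- pool[pool$final_score < q$final_score, ]
    ord <- order(pool$final_score, pool$name, pool$upc)
  } else {
    pool <- pool[pool$sodium_mg < q$sodium_mg, ]
    ord <- order(pool$sodium_mg, pool$final_score, pool$name, pool$upc)
  }
  list(upcs = utils::head(pool$upc[ord], max_results), message = NULL)
}

random_valid_panel <- function() {
  fat <- runif(1, 0, 40)
  carb <- runif(1, 0, 80)
  list(energy_kj = runif(1, 0, 3800), protein_g = runif(1, 0, 30),
       total_fat_g = fat, saturated_fat_g = fat * runif(1),
       carbohydrate_g = carb, sugars_g = carb * runif(1),
       sodium_mg = runif(1, 0, 3000), fiber_g = runif(1, 0, 15))
}
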