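# Every printed cut point for foods (per 100 g) and drinks (per 100 ml):
# green is inclusive of green_max, red requires strictly exceeding
# red_exceeds, amber fills the gap.
food_cuts <- list(
  total_fat = c(green_max = 3.0, red_exceeds = 20.0, portion = 21.0),
  saturated_fat = c(green_max = 1.5, red_exceeds = 5.0, portion = 6.0),
  sugars = c(green_max = 5.0, red_exceeds = 12.5, portion = 15.0),
  salt = c(green_max = 0.30, red_exceeds = 1.50, portion = 2.40)
)
drink_cuts <- list(
  total_fat = c(green_max = 1.5, red_exceeds = 10.0),
  saturated_fat = c(green_max = 0.75, red_exceeds = 2.5),
  sugars = c(green_max = 2.5, red_exceeds = 6.3),
  salt = c(green_max = 0.30, red_exceeds = 1.50)
)

test_that("classification reproduces every printed boundary exactly", {
  eps <- 1e-9
  for (basis in c("food", "drink")) {
    cuts <- if (basis == "food") food_cuts else drink_cuts
    is_drink <- basis == "drink"
    for (nu in names(cuts)) {
      g <- cuts[[nu]][["green_max"]]
      r <- cuts[[nu]][["red_exceeds"]]
      expect_identical(classify_nutrient(0, nu, is_drink), "green")
      expect_identical(classify_nutrient(g, nu, is_drink), "green")
      expect_identical(classify_nutrient(g + eps, nu, is_drink), "amber")
      expect_identical(classify_nutrient(r, nu, is_drink), "amber")
      expect_identical(classify_nutrient(r + eps, nu, is_drink), "red")
    }
  }
})

test_that("colour is monotone non-decreasing in the nutrient value", {
  rank <- c(green = 1L, amber = 2L, red = 3L)
  set.seed(404)
  for (is_drink in c(FALSE, TRUE)) {
    for (nu in c("total_fat", "saturated_fat", "sugars", "salt")) {
      vals <- sort(runif(200, 0, 30))
      cols <- classify_nutrient(vals, nu, is_drink)
      expect_true(all(diff(rank[cols]) >= 0),
                  info = sprintf("%s (drink=%s)", nu, is_drink))
    }
  }
})

test_that("labels classify on the right basis and derive salt from sodium", {
  # all four green: fat 1.0, satfat 0.5, sugars 4.0, salt 80*2.5/1000 = 0.2
  rec <- make_record(total_fat_g = 1, saturated_fat_g = 0.5, sugars_g = 4,
                     sodium_mg = 80, carbohydrate_g = 10)
  lab <- label_record(rec)
  expect_identical(unname(lab$colors),
                   rep("green", 4))
  expect_equal(lab$salt_g, 0.2)
  expect_identical(lab$basis, "per100g_food")
  expect_equal(lab$energy_kj, 500)

  # the same panel on a drink basis: sugars 4.0 g/100 ml is amber
  drink <- make_record(category_id = "juice", total_fat_g = 1,
                       saturated_fat_g = 0.5, sugars_g = 4, sodium_mg = 80,
                       carbohydrate_g = 10, pct_fvnl_nonconc = 90,
                       pct_fvnl_conc = 0, pct_non_fvnl = 10)
  drink$is_beverage <- TRUE
  lab2 <- label_record(drink)
  expect_identical(lab2$basis, "per100ml_drink")
  expect_identical(unname(lab2$colors["sugars"]), "amber")

  expect_error(label_record(make_record(sodium_mg = NA_real_)),
               regexp = "sodium_mg", class = "foodswap_input_error")
})

test_that("per-portion criteria upgrade foods to red, and only to red", {
  # 15 g/100 g is amber; a 150 g serving carries 22.5 g > 21.0 -> red
  rec <- make_record(total_fat_g = 15, saturated_fat_g = 1, sugars_g = 1,
                     sodium_mg = 10, carbohydrate_g = 30,
                     serving_size_g = 150)
  lab <- label_record(rec)
  expect_identical(unname(lab$colors["total_fat"]), "red")
  expect_identical(lab$portion_red_applied, "total_fat")

  # at exactly the portion threshold (21.0 g/portion) there is no upgrade
  rec$serving_size_g <- 140 # 15 * 140 / 100 = 21.0
  expect_identical(unname(label_record(rec)$colors["total_fat"]), "amber")

  # no serving size, no override
  rec$serving_size_g <- NA_real_
  expect_identical(unname(label_record(rec)$colors["total_fat"]), "amber")

  # drinks never get a portion override
  drink <- make_record(category_id = "softdrink", total_fat_g = 0,
                       saturated_fat_g = 0, sugars_g = 0, sodium_mg = 0,
                       carbohydrate_g = 0, serving_size_g = 600)
  drink$is_beverage <- TRUE
  lab3 <- label_record(drink)
  expect_identical(unname(lab3$colors), rep("green", 4))
  expect_length(lab3$portion_red_applied, 0)

  # property: with the override on, no colour ever moves away from red
  set.seed(11)
  for (i in 1:50) {
    p <- random_valid_panel()
    r <- make_record(total_fat_g = p$total_fat_g,
                     saturated_fat_g = p$saturated_fat_g,
                     carbohydrate_g = p$carbohydrate_g,
                     sugars_g = p$sugars_g, sodium_mg = p$sodium_mg,
                     serving_size_g = runif(1, 10, 400))
    with_override <- label_record(r)$colors
    without <- label_record(r, portion_override = FALSE)$colors
    rank <- c(green = 1L, amber = 2L, red = 3L)
    expect_true(all(rank[with_override] >= rank[without]))
    expect_true(all(with_override[with_override != without] == "red"))
  }
})

test_that("threshold configuration validates ordering and loads from YAML", {
  expect_error(
    foodswap:::new_thresholds(
      tibble::tibble(nutrient = c("total_fat", "saturated_fat", "sugars", "salt"),
                     green_max = c(5, 1.5, 5, 0.3),
                     red_exceeds = c(4, 5, 12.5, 1.5),
                     portion_red_exceeds = c(21, 6, 15, 2.4)),
      default_thresholds()$drink),
    class = "foodswap_validation_error")

  path <- withr::local_tempfile(fileext = ".yaml")
  thr <- default_thresholds()
  cfg <- list(
    food = setNames(lapply(seq_len(4), function(i) list(
      green_max = thr$food$green_max[i],
      red_exceeds = thr$food$red_exceeds[i],
      portion_red_exceeds = thr$food$portion_red_exceeds[i])),
      thr$food$nutrient),
    drink = setNames(lapply(seq_len(4), function(i) list(
      green_max = thr$drink$green_max[i],
      red_exceeds = thr$drink$red_exceeds[i])), thr$drink$nutrient)
  )
  yaml::write_yaml(cfg, path)
  expect_equal(read_thresholds(path)$food, thr$food)
})
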