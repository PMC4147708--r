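test_that("scoring category: beverages 1; oils 3; cheese by calcium cutoff", {
  db <- tiny_db()
  cats <- db$categories
  expect_equal(determine_category(lookup_upc(db, "00000056"), cats), 1L)
  expect_equal(determine_category(lookup_upc(db, "00000049"), cats), 3L)
  expect_equal(determine_category(lookup_upc(db, "00000001"), cats), 2L)

  cheese <- lookup_upc(db, "00000025")
  cheese$calcium_mg <- 400
  expect_equal(determine_category(cheese, cats), 3L)
  cheese$calcium_mg <- 320 # the cutoff is strict
  expect_equal(determine_category(cheese, cats), 2L)
  cheese$calcium_mg <- 321
  expect_equal(determine_category(cheese, cats), 3L)

  cheese$calcium_mg <- NA_real_
  expect_error(determine_category(cheese, cats),
               class = "foodswap_imputation_error")
})

test_that("baseline points follow the step tables and caps", {
  zero <- list(energy_kj = 0, saturated_fat_g = 0, sugars_g = 0,
               sodium_mg = 0)
  b <- baseline_points(zero)
  expect_equal(unlist(b), c(energy = 0, satfat = 0, sugars = 0, sodium = 0,
                            total = 0))

  huge <- list(energy_kj = 1e6, saturated_fat_g = 1e6, sugars_g = 1e6,
               sodium_mg = 1e6)
  b2 <- baseline_points(huge)
  expect_equal(b2$energy, 10)   # caps as printed
  expect_equal(b2$satfat, 30)
  expect_equal(b2$sugars, 10)
  expect_equal(b2$sodium, 30)
  expect_equal(b2$total, 80)

  # 670 kJ sits exactly on the second step: strictly-exceed semantics
  # award one point (oracle: walk the raw table)
  tables <- default_point_tables()
  expect_equal(baseline_points(list(energy_kj = 670, saturated_fat_g = 0,
                                    sugars_g = 0, sodium_mg = 0))$energy,
               oracle_step_points(670, tables$energy_kj))
  expect_equal(oracle_step_points(670, tables$energy_kj), 1L)

  expect_error(baseline_points(list(energy_kj = 100, saturated_fat_g = 0,
                                    sugars_g = 0)),
               regexp = "sodium_mg", class = "foodswap_input_error")
})

test_that("fvnl percentage implements the double-weighted formula", {
  expect_equal(fvnl_percent(100, 0, 0), 100)
  expect_equal(fvnl_percent(0, 0, 100), 0)
  expect_equal(fvnl_percent(40, 10, 50), 100 * 60 / 110)
  expect_error(fvnl_percent(0, 0, 0), class = "foodswap_input_error")
  expect_error(fvnl_percent(-1, 0, 50), class = "foodswap_input_error")
})

test_that("modifying points: V value set, P and F caps", {
  panel0 <- list(protein_g = 0, fiber_g = 0)
  expect_equal(modifying_points(panel0, 0), list(v = 0L, p = 0L, f = 0L))
  expect_equal(modifying_points(panel0, 100)$v, 8L)
  expect_equal(modifying_points(list(protein_g = 1e6, fiber_g = 1e6), 0),
               list(v = 0L, p = 5L, f = 2L))

  # V points take only the printed values, whatever the percentage
  set.seed(21)
  for (pct in c(runif(200, 0, 100), 40, 60, 80, 100)) {
    v <- modifying_points(panel0, pct)$v
    expect_true(v %in% c(0L, 1L, 2L, 5L, 8L))
    expect_equal(v, oracle_v_points(pct))
  }

  expect_error(modifying_points(list(protein_g = NA_real_, fiber_g = 0), 0),
               class = "foodswap_input_error")
  expect_error(modifying_points(list(protein_g = 1, fiber_g = NA_real_), 0),
               class = "foodswap_input_error")
})

test_that("protein-cap rule is off by default and withholds P when enabled", {
  tables <- default_point_tables()
  panel <- list(protein_g = 10, fiber_g = 0)
  expect_equal(modifying_points(panel, 0, tables = tables, baseline = 20)$p,
               5L)
  tables$protein_cap_rule$enabled <- TRUE
  expect_equal(modifying_points(panel, 0, tables = tables, baseline = 20)$p,
               0L)
  # high V points release the cap
  expect_equal(modifying_points(panel, 90, tables = tables, baseline = 20)$p,
               5L)
  # baseline at or below the threshold is unaffected
  expect_equal(modifying_points(panel, 0, tables = tables, baseline = 13)$p,
               5L)
})

test_that("final score satisfies the identity and composes the parts", {
  db <- score_database(tiny_db())
  s <- db$scores
  expect_true(all(s$final_score ==
                    s$baseline_points - s$v_points - s$p_points - s$f_points))
  expect_true(all(s$baseline_points ==
                    s$energy_points + s$satfat_points + s$sugars_points +
                      s$sodium_points))

  # an all-zero panel scores zero
  zero_rec <- make_record(upc = "00000101", energy_kj = 0, protein_g = 0,
                          total_fat_g = 0, saturated_fat_g = 0,
                          carbohydrate_g = 0, sugars_g = 0, sodium_mg = 0,
                          fiber_g = 0)
  sc <- score_record(zero_rec, tiny_db())
  expect_equal(sc$final_score, 0L)
  expect_equal(sc$baseline$total, 0L)

  # imputed fields are flagged on the score
  soft_cheese <- s[s$upc == "00000032", ]
  expect_match(soft_cheese$imputed, "calcium_mg")
  expect_match(soft_cheese$imputed, "fiber_g")
})

test_that("worked example: baseline 12 minus V 2, P 1, F 1 gives 8", {
  # energy 1400 kJ -> 4, satfat 3.5 g -> 3, sugars 10 g -> 2, sodium 280 -> 3
  rec <- make_record(upc = "00000202", category_id = "bread",
                     energy_kj = 1400, saturated_fat_g = 3.5,
                     total_fat_g = 6, sugars_g = 10, carbohydrate_g = 40,
                     sodium_mg = 280, protein_g = 2, fiber_g = 1,
                     pct_fvnl_nonconc = 65, pct_fvnl_conc = 0,
                     pct_non_fvnl = 35)
  sc <- score_record(rec, tiny_db())
  expect_equal(sc$baseline$total, 12L)
  expect_equal(sc$v_points, 2L)
  expect_equal(sc$p_points, 1L)
  expect_equal(sc$f_points, 1L)
  expect_equal(sc$final_score, 8L)
})

test_that("scores match a brute-force recomputation from the raw tables", {
  tables <- default_point_tables()
  db <- tiny_db()
  set.seed(33)
  for (i in 1:60) {
    p <- random_valid_panel()
    rec <- make_record(upc = sprintf("%08d", 300 + i),
                       energy_kj = p$energy_kj, protein_g = p$protein_g,
                       total_fat_g = p$total_fat_g,
                       saturated_fat_g = p$saturated_fat_g,
                       carbohydrate_g = p$carbohydrate_g,
                       sugars_g = p$sugars_g, sodium_mg = p$sodium_mg,
                       fiber_g = p$fiber_g)
    sc <- score_record(rec, db)
    expected <- oracle_step_points(p$energy_kj, tables$energy_kj) +
      oracle_step_points(p$saturated_fat_g, tables$saturated_fat_g) +
      oracle_step_points(p$sugars_g, tables$sugars_g) +
      oracle_step_points(p$sodium_mg, tables$sodium_mg) -
      oracle_step_points(p$protein_g, tables$protein_g) -
      oracle_step_points(p$fiber_g, tables$fiber_g)
    expect_equal(sc$final_score, expected)
  }
})

test_that("weak monotonicity: worse nutrients never lower the score", {
  db <- tiny_db()
  set.seed(55)
  for (i in 1:40) {
    p <- random_valid_panel()
    base <- make_record(upc = "00000400", energy_kj = p$energy_kj,
                        protein_g = p$protein_g,
                        total_fat_g = p$total_fat_g,
                        saturated_fat_g = p$saturated_fat_g,
                        carbohydrate_g = p$carbohydrate_g,
                        sugars_g = p$sugars_g, sodium_mg = p$sodium_mg,
                        fiber_g = p$fiber_g)
    s0 <- score_record(base, db)$final_score

    saltier <- base
    saltier$sodium_mg <- base$sodium_mg + runif(1, 0, 2000)
    expect_gte(score_record(saltier, db)$final_score, s0)

    sweeter <- base
    sweeter$sugars_g <- base$sugars_g + runif(1, 0, 50)
    sweeter$carbohydrate_g <- sweeter$sugars_g + base$carbohydrate_g
    expect_gte(score_record(sweeter, db)$final_score, s0)

    leaner <- base
    leaner$protein_g <- base$protein_g + runif(1, 0, 20)
    expect_lte(score_record(leaner, db)$final_score, s0)

    fibrous <- base
    fibrous$fiber_g <- base$fiber_g + runif(1, 0, 10)
    expect_lte(score_record(fibrous, db)$final_score, s0)
  }
})

test_that("point tables load from config with increments or thresholds", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    energy_kj = list(increment = 335, cap = 10),
    sugars_g = list(thresholds = c(5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45)),
    protein_cap_rule = list(enabled = TRUE)
  ), path)
  tables <- read_point_tables(path)
  expect_equal(tables$energy_kj, 335 * (1:10))
  expect_equal(tables$sugars_g[1], 5)
  expect_true(tables$protein_cap_rule$enabled)
  expect_equal(tables$saturated_fat_g, 1 * (1:30)) # defaults retained
})
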