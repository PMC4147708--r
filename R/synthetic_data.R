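# Archetype profiles loosely mimicking common supermarket categories, so
# that all three scoring categories (beverages; ordinary foods; oils,
# spreads and high-calcium cheese) and all imputation paths are exercised.
category_archetypes <- function() {
  list(
    list(name = "Bread", is_beverage = FALSE, fiber_possible = TRUE,
         fvnl_possible = FALSE, default_fvnl_pct = NA_real_,
         npsc_category3_member = FALSE, is_cheese = FALSE,
         switch_excluded = FALSE,
         energy = c(900, 1300), protein = c(7, 12), fat = c(1, 6),
         carb = c(38, 55), sugar_frac = c(0.02, 0.15),
         sodium = c(300, 600), fiber = c(2, 8), calcium = NULL),
    list(name = "Breakfast cereal", is_beverage = FALSE,
         fiber_possible = TRUE, fvnl_possible = FALSE,
         default_fvnl_pct = NA_real_, npsc_category3_member = FALSE,
         is_cheese = FALSE, switch_excluded = FALSE,
         energy = c(1400, 1700), protein = c(6, 13), fat = c(1, 15),
         carb = c(55, 85), sugar_frac = c(0.05, 0.45),
         sodium = c(5, 700), fiber = c(3, 15), calcium = NULL),
    list(name = "Cheese", is_beverage = FALSE, fiber_possible = FALSE,
         fvnl_possible = FALSE, default_fvnl_pct = NA_real_,
         npsc_category3_member = FALSE, is_cheese = TRUE,
         switch_excluded = FALSE,
         energy = c(1100, 1750), protein = c(18, 28), fat = c(18, 36),
         carb = c(0, 5), sugar_frac = c(0, 0.9),
         sodium = c(450, 1000), fiber = c(0, 0), calcium = c(150, 900)),
    list(name = "Oils and margarine", is_beverage = FALSE,
         fiber_possible = FALSE, fvnl_possible = FALSE,
         default_fvnl_pct = NA_real_, npsc_category3_member = TRUE,
         is_cheese = FALSE, switch_excluded = FALSE,
         energy = c(2200, 3700), protein = c(0, 1), fat = c(55, 100),
         carb = c(0, 1), sugar_frac = c(0, 0.5),
         sodium = c(0, 750), fiber = c(0, 0), calcium = NULL),
    list(name = "Sugar-sweetened soft drinks", is_beverage = TRUE,
         fiber_possible = FALSE, fvnl_possible = FALSE,
         default_fvnl_pct = NA_real_, npsc_category3_member = FALSE,
         is_cheese = FALSE, switch_excluded = TRUE,
         standard_message = "Sugar-free drinks and water are healthier choices",
         energy = c(120, 210), protein = c(0, 0.5), fat = c(0, 0.2),
         carb = c(6, 13), sugar_frac = c(0.85, 1),
         sodium = c(1, 40), fiber = c(0, 0), calcium = NULL),
    list(name = "Fruit juice", is_beverage = TRUE, fiber_possible = FALSE,
         fvnl_possible = TRUE, default_fvnl_pct = 95,
         npsc_category3_member = FALSE, is_cheese = FALSE,
         switch_excluded = FALSE,
         energy = c(140, 200), protein = c(0.1, 1), fat = c(0, 0.5),
         carb = c(8, 12), sugar_frac = c(0.8, 1),
         sodium = c(1, 25), fiber = c(0, 0.6), calcium = NULL),
    list(name = "Yogurt", is_beverage = FALSE, fiber_possible = FALSE,
         fvnl_possible = TRUE, default_fvnl_pct = 8,
         npsc_category3_member = FALSE, is_cheese = FALSE,
         switch_excluded = FALSE,
         energy = c(250, 600), protein = c(3, 11), fat = c(0.1, 10),
         carb = c(4, 20), sugar_frac = c(0.5, 1),
         sodium = c(30, 90), fiber = c(0, 0.5), calcium = c(100, 250)),
    list(name = "Snack bars", is_beverage = FALSE, fiber_possible = TRUE,
         fvnl_possible = TRUE, default_fvnl_pct = 25,
         npsc_category3_member = FALSE, is_cheese = FALSE,
         switch_excluded = FALSE,
         energy = c(1400, 2000), protein = c(4, 15), fat = c(5, 25),
         carb = c(40, 70), sugar_frac = c(0.2, 0.7),
         sodium = c(20, 400), fiber = c(2, 12), calcium = NULL),
    list(name = "Canned vegetables", is_beverage = FALSE,
         fiber_possible = TRUE, fvnl_possible = TRUE,
         default_fvnl_pct = 80, npsc_category3_member = FALSE,
         is_cheese = FALSE, switch_excluded = FALSE,
         energy = c(80, 400), protein = c(1, 6), fat = c(0, 2),
         carb = c(2, 18), sugar_frac = c(0.1, 0.6),
         sodium = c(5, 450), fiber = c(1, 7), calcium = NULL),
    list(name = "Chocolate confectionery", is_beverage = FALSE,
         fiber_possible = FALSE, fvnl_possible = FALSE,
         default_fvnl_pct = NA_real_, npsc_category3_member = FALSE,
         is_cheese = FALSE, switch_excluded = FALSE,
         energy = c(1900, 2400), protein = c(4, 9), fat = c(20, 40),
         carb = c(45, 65), sugar_frac = c(0.6, 0.95),
         sodium = c(20, 250), fiber = c(0, 0), calcium = NULL)
  )
}

#' Configuration for the synthetic database generator
#'
#' @param n_categories Number of categories to generate.
#' @param products_per_category Integer range `c(min, max)`; the per-category
#'   product count is drawn uniformly from it.
#' @param missing_fiber_rate,missing_calcium_rate,missing_fvnl_rate
#'   Per-record probabilities that the corresponding optional field is
#'   absent.
#' @param n_excluded_categories Number of switch-excluded categories (with
#'   a standard advisory message) to include.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_categories = 10L,
                             products_per_category = c(10L, 30L),
                             missing_fiber_rate = 0.3,
                             missing_calcium_rate = 0.4,
                             missing_fvnl_rate = 0.9,
                             n_excluded_categories = 1L,
                             seed = 1L) {
  cfg <- list(
    n_categories = as.integer(n_categories),
    products_per_category = as.integer(products_per_category),
    missing_fiber_rate = missing_fiber_rate,
    missing_calcium_rate = missing_calcium_rate,
    missing_fvnl_rate = missing_fvnl_rate,
    n_excluded_categories = as.integer(n_excluded_categories),
    seed = as.integer(seed)
  )
  rates <- c(cfg$missing_fiber_rate, cfg$missing_calcium_rate,
             cfg$missing_fvnl_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("Missingness rates must lie in [0, 1].",
          class = "foodswap_input_error")
  }
  if (length(cfg$products_per_category) != 2L ||
      any(cfg$products_per_category < 1L) ||
      cfg$products_per_category[1] > cfg$products_per_category[2]) {
    abort("products_per_category must be an increasing positive range.",
          class = "foodswap_input_error")
  }
  if (cfg$n_categories < 1L) {
    abort("At least one category is required.",
          class = "foodswap_input_error")
  }
  if (cfg$n_excluded_categories > cfg$n_categories) {
    abort("More excluded categories than categories.",
          class = "foodswap_input_error")
  }
  structure(cfg, class = "generator_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a seeded synthetic food database
#'
#' Builds a database with realistic structure — supermarket-style
#' categories, archetype-specific nutrient ranges, controlled missingness
#' of fibre, calcium and fvnl data, valid GTIN-13 barcodes, and at least
#' one switch-excluded category with a standard message when requested.
#' Output is deterministic given the configuration and passes all database
#' invariants; the configuration is attached as metadata.
#'
#' @param cfg A [generator_config()].
#' @return A `food_db` object with a `generator` attribute recording the
#'   seed and configuration.
#' @export
generate_database <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    arch <- category_archetypes()
    soft_drink <- which(vapply(arch, function(a) isTRUE(a$switch_excluded),
                               logical(1)))[1]
    # excluded categories first, then cycle through the archetype list
    idx <- c(rep(soft_drink, cfg$n_excluded_categories),
             rep(seq_along(arch),
                 length.out = cfg$n_categories - cfg$n_excluded_categories))
    categories <- bind_rows(lapply(seq_along(idx), function(i) {
      a <- arch[[idx[i]]]
      excluded <- a$switch_excluded && i <= cfg$n_excluded_categories
      tibble(
        category_id = sprintf("CAT%03d", i),
        name = sprintf("%s %d", a$name, i),
        is_beverage = a$is_beverage,
        fiber_possible = a$fiber_possible,
        fvnl_possible = a$fvnl_possible,
        default_fvnl_pct = a$default_fvnl_pct,
        npsc_category3_member = a$npsc_category3_member,
        is_cheese = a$is_cheese,
        switch_excluded = excluded,
        standard_message = if (excluded) a$standard_message else NA_character_
      )
    }))

    upc_offset <- sample(9e6, 1)
    serial <- 0L
    records <- list()
    for (i in seq_along(idx)) {
      a <- arch[[idx[i]]]
      n <- cfg$products_per_category[1] +
        sample.int(diff(cfg$products_per_category) + 1L, 1L) - 1L
      for (j in seq_len(n)) {
        serial <- serial + 1L
        payload <- sprintf("93%010d", upc_offset + serial)
        fat <- runif1(a$fat)
        carb <- runif1(a$carb)
        fiber <- runif1(a$fiber)
        if (stats::runif(1) < cfg$missing_fiber_rate) fiber <- NA_real_
        calcium <- if (is.null(a$calcium)) NA_real_ else runif1(a$calcium)
        if (!is.na(calcium) &&
            stats::runif(1) < cfg$missing_calcium_rate) calcium <- NA_real_
        has_comp <- a$fvnl_possible &&
          stats::runif(1) >= cfg$missing_fvnl_rate
        nonconc <- conc <- nonf <- NA_real_
        if (has_comp) {
          nonconc <- min(100, max(0, a$default_fvnl_pct +
                                    stats::runif(1, -15, 10)))
          conc <- stats::runif(1, 0, min(5, 100 - nonconc))
          nonf <- max(0, 100 - nonconc - conc)
        }
        serving <- if (stats::runif(1) < 0.85) {
          if (a$is_beverage) sample(c(250, 330, 375, 600), 1)
          else round(stats::runif(1, 20, 150))
        } else NA_real_
        records[[serial]] <- tibble(
          upc = paste0(payload, gtin_check_digit(payload)),
          name = sprintf("%s product %d", a$name, serial),
          brand = sprintf("Brand %d", ((serial - 1L) %% 40L) + 1L),
          category_id = categories$category_id[i],
          is_beverage = a$is_beverage,
          serving_size_g = serving,
          energy_kj = round(runif1(a$energy), 1),
          protein_g = round(runif1(a$protein), 2),
          total_fat_g = round(fat, 2),
          saturated_fat_g = round(fat * stats::runif(1, 0.15, 0.9), 2),
          carbohydrate_g = round(carb, 2),
          sugars_g = round(carb * runif1(a$sugar_frac), 2),
          sodium_mg = round(runif1(a$sodium), 1),
          fiber_g = if (is.na(fiber)) NA_real_ else round(fiber, 2),
          calcium_mg = if (is.na(calcium)) NA_real_ else round(calcium, 1),
          pct_fvnl_nonconc = if (has_comp) round(nonconc, 1) else NA_real_,
          pct_fvnl_conc = if (has_comp) round(conc, 1) else NA_real_,
          pct_non_fvnl = if (has_comp) round(nonf, 1) else NA_real_,
          provenance = "surveyed"
        )
      }
    }
    records <- bind_rows(records)

    # ensure imputation stays resolvable: at least one observed fibre value
    # per fibre-containing category, one calcium value per cheese category
    for (i in seq_along(idx)) {
      a <- arch[[idx[i]]]
      rows <- which(records$category_id == categories$category_id[i])
      if (a$fiber_possible && all(is.na(records$fiber_g[rows]))) {
        records$fiber_g[rows[1]] <- round(runif1(a$fiber), 2)
      }
      if (a$is_cheese && all(is.na(records$calcium_mg[rows]))) {
        records$calcium_mg[rows[1]] <- round(runif1(a$calcium), 1)
      }
    }

    db <- food_database(records, categories)
    attr(db, "generator") <- list(seed = cfg$seed, config = unclass(cfg))
    db
  })
}
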