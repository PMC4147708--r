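TL_NUTRIENTS <- c("total_fat", "saturated_fat", "sugars", "salt")

#' Default traffic-light thresholds
#'
#' The UK FSA front-of-pack criteria: per-100 g cut points and per-portion
#' red criteria for foods, and per-100 ml cut points for drinks. A nutrient
#' is green when at or below `green_max`, red when strictly above
#' `red_exceeds` (or, for foods with a known serving size, when the
#' per-portion amount strictly exceeds `portion_red_exceeds`), and amber in
#' between. Boundaries are inclusive for green and amber exactly as
#' printed: e.g. total fat at 3.0 g/100 g is green, 20.0 is amber, 20.01 is
#' red.
#'
#' @return A `tl_thresholds` object: a list with `food` and `drink`
#'   threshold tables.
#' @export
default_thresholds <- function() {
  food <- tibble(
    nutrient = TL_NUTRIENTS,
    green_max = c(3.0, 1.5, 5.0, 0.30),
    red_exceeds = c(20.0, 5.0, 12.5, 1.50),
    portion_red_exceeds = c(21.0, 6.0, 15.0, 2.40)
  )
  drink <- tibble(
    nutrient = TL_NUTRIENTS,
    green_max = c(1.5, 0.75, 2.5, 0.30),
    red_exceeds = c(10.0, 2.5, 6.3, 1.50)
  )
  new_thresholds(food, drink)
}

new_thresholds <- function(food, drink) {
  food <- as_tibble(food)
  drink <- as_tibble(drink)
  for (tab in list(food, drink)) {
    stopifnot(setequal(tab$nutrient, TL_NUTRIENTS))
    if (any(tab$green_max >= tab$red_exceeds)) {
      abort("Thresholds must satisfy green_max < red_exceeds for every nutrient.",
            class = "foodswap_validation_error")
    }
  }
  if (any(food$portion_red_exceeds <= 0)) {
    abort("Per-portion red criteria must be positive.",
          class = "foodswap_validation_error")
  }
  structure(list(food = food, drink = drink), class = "tl_thresholds")
}

#' Read a traffic-light threshold configuration
#'
#' Loads a YAML or JSON file with `food` and `drink` tables (lists keyed by
#' nutrient with `green_max`, `red_exceeds` and, for food,
#' `portion_red_exceeds`) and validates the ordering invariant.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `tl_thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  to_tab <- function(x, portion) {
    tab <- tibble(
      nutrient = names(x),
      green_max = vapply(x, function(r) as.numeric(r$green_max), 1,
                         USE.NAMES = FALSE),
      red_exceeds = vapply(x, function(r) as.numeric(r$red_exceeds), 1,
                           USE.NAMES = FALSE)
    )
    if (portion) {
      tab$portion_red_exceeds <-
        vapply(x, function(r) as.numeric(r$portion_red_exceeds), 1,
               USE.NAMES = FALSE)
    }
    tab
  }
  new_thresholds(to_tab(cfg$food, TRUE), to_tab(cfg$drink, FALSE))
}

#' Classify one nutrient value as green, amber or red
#'
#' @param value_per_100 Nutrient amount per 100 g (food) or per 100 ml
#'   (drink); for salt, grams of salt equivalent (see
#'   [salt_from_sodium()]).
#' @param nutrient One of `"total_fat"`, `"saturated_fat"`, `"sugars"`,
#'   `"salt"`.
#' @param is_drink Use the drink thresholds?
#' @param thresholds A `tl_thresholds` object.
#' @return A character vector of colours (`"green"`, `"amber"`, `"red"`),
#'   vectorised over `value_per_100`.
#' @export
#' @examples
#' classify_nutrient(3.0, "total_fat")          # "green" (inclusive boundary)
#' classify_nutrient(6.4, "sugars", is_drink = TRUE)  # "red"
classify_nutrient <- function(value_per_100, nutrient = TL_NUTRIENTS,
                              is_drink = FALSE,
                              thresholds = default_thresholds()) {
  nutrient <- match.arg(nutrient)
  stopifnot(inherits(thresholds, "tl_thresholds"))
  if (any(is.na(value_per_100)) || any(value_per_100 < 0)) {
    abort("Nutrient values must be non-negative and non-missing.",
          class = "foodswap_input_error")
  }
  tab <- if (is_drink) thresholds$drink else thresholds$food
  row <- tab[tab$nutrient == nutrient, ]
  ifelse(value_per_100 <= row$green_max, "green",
         ifelse(value_per_100 > row$red_exceeds, "red", "amber"))
}

#' Traffic-light label for a product record
#'
#' Classifies total fat, saturated fat, sugars and salt on the per-100 g
#' (food) or per-100 ml (drink) basis, and reports energy as an uncoloured
#' fifth display. Salt is derived from declared sodium before
#' classification. For foods with a known serving size, a nutrient whose
#' per-portion amount strictly exceeds the per-portion red criterion is
#' upgraded to red regardless of its per-100 g colour; drinks have no
#' per-portion criteria.
#'
#' @param record A one-row record tibble (e.g. from [lookup_upc()]).
#' @param thresholds A `tl_thresholds` object.
#' @param portion_override Apply the per-portion red criteria for foods
#'   when a serving size is present? Default `TRUE`.
#' @return A `traffic_light_label` object: colours per nutrient, the
#'   uncoloured energy value, the basis used, and which nutrients were
#'   upgraded by the per-portion rule.
#' @export
label_record <- function(record, thresholds = default_thresholds(),
                         portion_override = TRUE) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1L)
  needed <- c("total_fat_g", "saturated_fat_g", "sugars_g", "sodium_mg")
  missing <- needed[vapply(needed, function(col) {
    is.null(record[[col]]) || is.na(record[[col]])
  }, logical(1))]
  if (length(missing)) {
    abort(sprintf("Cannot label '%s': missing %s.",
                  record[["upc"]] %||% "<record>",
                  paste(missing, collapse = ", ")),
          class = "foodswap_input_error")
  }
  is_drink <- isTRUE(record$is_beverage)
  values <- c(
    total_fat = record$total_fat_g,
    saturated_fat = record$saturated_fat_g,
    sugars = record$sugars_g,
    salt = salt_from_sodium(record$sodium_mg)
  )
  colors <- vapply(TL_NUTRIENTS, function(nu) {
    classify_nutrient(values[[nu]], nu, is_drink, thresholds)
  }, character(1))

  portion_red <- character()
  serving <- record[["serving_size_g"]] %||% NA_real_
  if (portion_override && !is_drink && !is.na(serving)) {
    per_portion <- values * serving / 100
    over <- per_portion > setNames(thresholds$food$portion_red_exceeds,
                                   thresholds$food$nutrient)[TL_NUTRIENTS]
    portion_red <- TL_NUTRIENTS[over]
    colors[over] <- "red"
  }

  structure(list(
    upc = record[["upc"]] %||% NA_character_,
    basis = if (is_drink) "per100ml_drink" else "per100g_food",
    colors = colors,
    energy_kj = record[["energy_kj"]] %||% NA_real_,
    salt_g = unname(values[["salt"]]),
    portion_red_applied = portion_red
  ), class = "traffic_light_label")
}

#' @export
print.traffic_light_label <- function(x, ...) {
  cat(sprintf("<traffic_light_label> %s (%s)\n", x$upc, x$basis))
  for (nu in names(x$colors)) {
    flag <- if (nu %in% x$portion_red_applied) " [per-portion red]" else ""
    cat(sprintf("  %-14s %s%s\n", nu, x$colors[[nu]], flag))
  }
  cat(sprintf("  %-14s %.0f kJ (no colour)\n", "energy", x$energy_kj))
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x
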