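#' Default nutrient-profile point tables
#'
#' The scoring scheme allocates baseline points for energy, saturated fat,
#' total sugars and sodium, offset by modifying points for fruit, vegetable,
#' nut and legume (fvnl) content, protein and fibre. The printed scheme
#' constrains the caps (energy 0--10, saturated fat 0--30, sugars 0--10,
#' sodium 0--30, protein up to 5, fibre up to 2) and the V-point value set
#' \{0, 1, 2, 5, 8\}; the per-point increments default to the published FSANZ
#' granularity: one point per 335 kJ energy, 1 g saturated fat, 4.5 g
#' sugars, 90 mg sodium, 1.6 g protein and 0.9 g fibre. A component scores
#' k points when its amount strictly exceeds the k-th step threshold,
#' capped at the table length.
#'
#' The V-point lookup awards 1/2/5 points above 40/60/80 per cent fvnl and
#' the maximum 8 points at 100 per cent. The FSANZ protein-cap rule (P
#' points withheld when baseline points exceed a threshold unless V points
#' are at least 5) is representable but disabled by default.
#'
#' @return An `npsc_point_tables` object.
#' @export
default_point_tables <- function() {
  new_point_tables(list(
    energy_kj = 335 * (1:10),
    saturated_fat_g = 1 * (1:30),
    sugars_g = 4.5 * (1:10),
    sodium_mg = 90 * (1:30),
    protein_g = 1.6 * (1:5),
    fiber_g = 0.9 * (1:2),
    v_lookup = list(cuts = c(40, 60, 80), points = c(1, 2, 5),
                    full_points = 8),
    protein_cap_rule = list(enabled = FALSE, baseline_threshold = 13,
                            v_required = 5)
  ))
}

new_point_tables <- function(x) {
  step_names <- c("energy_kj", "saturated_fat_g", "sugars_g", "sodium_mg",
                  "protein_g", "fiber_g")
  stopifnot(all(step_names %in% names(x)))
  for (nm in step_names) {
    steps <- as.numeric(x[[nm]])
    if (length(steps) == 0 || is.unsorted(steps, strictly = FALSE) ||
        any(steps < 0)) {
      abort(sprintf("Step table '%s' must be non-negative and monotone non-decreasing.", nm),
            class = "foodswap_validation_error")
    }
    x[[nm]] <- steps
  }
  v <- x$v_lookup
  stopifnot(length(v$cuts) == length(v$points),
            !is.unsorted(v$cuts, strictly = TRUE),
            !is.unsorted(v$points, strictly = TRUE))
  structure(x, class = "npsc_point_tables")
}

#' Read a point-table configuration
#'
#' Loads a YAML or JSON point-table file. Step tables may be given either
#' as explicit threshold vectors (`thresholds: [335, 670, ...]`) or as
#' `increment`/`cap` pairs.
#'
#' @param path Path to a YAML or JSON file.
#' @return An `npsc_point_tables` object.
#' @export
read_point_tables <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  tables <- unclass(default_point_tables())
  for (nm in intersect(names(cfg), names(tables))) {
    entry <- cfg[[nm]]
    if (nm %in% c("v_lookup", "protein_cap_rule")) {
      tables[[nm]] <- utils::modifyList(tables[[nm]], entry)
    } else if (!is.null(entry$thresholds)) {
      tables[[nm]] <- as.numeric(entry$thresholds)
    } else if (!is.null(entry$increment)) {
      tables[[nm]] <- entry$increment * seq_len(entry$cap)
    } else {
      tables[[nm]] <- as.numeric(entry)
    }
  }
  new_point_tables(tables)
}

# points = number of step thresholds strictly exceeded, capped by length
step_points <- function(value, steps) {
  vapply(value, function(v) sum(v > steps), integer(1))
}

#' Determine the nutrient-profile scoring category
#'
#' Beverages score in category 1. Category 3 holds edible oils, spreads,
#' margarine and butter (flagged at category level) together with cheese
#' and processed cheese containing strictly more than 320 mg calcium per
#' 100 g; cheese at or below the cutoff scores as ordinary food. Everything
#' else is category 2.
#'
#' @param record A one-row record tibble.
#' @param categories The category table of the database.
#' @return Integer 1, 2 or 3.
#' @export
determine_category <- function(record, categories) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1L)
  if (isTRUE(record$is_beverage)) return(1L)
  cat_row <- categories[categories$category_id == record$category_id, ]
  if (nrow(cat_row) == 0L) {
    abort(sprintf("Unknown category_id '%s'.", record$category_id),
          class = "foodswap_input_error")
  }
  if (isTRUE(cat_row$is_cheese)) {
    calcium <- record$calcium_mg
    if (is.null(calcium) || is.na(calcium)) {
      abort(sprintf(
        "Record '%s' is in cheese category '%s' but has no calcium value; impute before scoring.",
        record$upc, record$category_id),
        class = "foodswap_imputation_error")
    }
    return(if (calcium > 320) 3L else 2L)
  }
  if (isTRUE(cat_row$npsc_category3_member)) return(3L)
  2L
}

#' Baseline points for energy, saturated fat, sugars and sodium
#'
#' Each component is looked up in its monotone step table and capped; the
#' total is the sum of the four components.
#'
#' @param panel A one-row tibble (or named list) with `energy_kj`,
#'   `saturated_fat_g`, `sugars_g`, `sodium_mg` per 100 g/ml.
#' @param npsc_category Scoring category 1, 2 or 3 (reserved for
#'   category-specific tables; the default tables are shared).
#' @param tables An `npsc_point_tables` object.
#' @return A list with components `energy`, `satfat`, `sugars`, `sodium`
#'   and `total`.
#' @export
baseline_points <- function(panel, npsc_category = 2L,
                            tables = default_point_tables()) {
  needed <- c("energy_kj", "saturated_fat_g", "sugars_g", "sodium_mg")
  for (col in needed) {
    if (is.null(panel[[col]]) || is.na(panel[[col]])) {
      abort(sprintf("Baseline points require %s.", col),
            class = "foodswap_input_error")
    }
  }
  out <- list(
    energy = step_points(panel$energy_kj, tables$energy_kj),
    satfat = step_points(panel$saturated_fat_g, tables$saturated_fat_g),
    sugars = step_points(panel$sugars_g, tables$sugars_g),
    sodium = step_points(panel$sodium_mg, tables$sodium_mg)
  )
  out$total <- out$energy + out$satfat + out$sugars + out$sodium
  out
}

#' Percentage fruit, vegetable, nut and legume content
#'
#' Computes the fvnl percentage from the declared composition, with
#' concentrated fruit and vegetable components double-weighted:
#' `100 * (nonconc + 2*conc) / (nonconc + 2*conc + non_fvnl)`.
#'
#' @param pct_nonconc Per cent non-concentrated fvnl ingredients.
#' @param pct_conc Per cent concentrated fruit or vegetable ingredients.
#' @param pct_non_fvnl Per cent non-fvnl ingredients.
#' @return The fvnl percentage in `[0, 100]`.
#' @export
#' @examples
#' fvnl_percent(40, 10, 50) # 100 * 60 / 110 = 54.55
fvnl_percent <- function(pct_nonconc, pct_conc, pct_non_fvnl) {
  if (any(c(pct_nonconc, pct_conc, pct_non_fvnl) < 0)) {
    abort("fvnl composition components must be non-negative.",
          class = "foodswap_input_error")
  }
  weighted <- pct_nonconc + 2 * pct_conc
  denom <- weighted + pct_non_fvnl
  if (denom == 0) {
    abort("fvnl composition is all zero; percentage undefined.",
          class = "foodswap_input_error")
  }
  100 * weighted / denom
}

v_points_from_pct <- function(fvnl_pct, tables) {
  v <- tables$v_lookup
  if (fvnl_pct >= 100) return(as.integer(v$full_points))
  as.integer(c(0, v$points)[findInterval(fvnl_pct, v$cuts,
                                         left.open = TRUE) + 1L])
}

#' Modifying points for fvnl content, protein and fibre
#'
#' V points come from the configured fvnl-percentage lookup (restricted to
#' the value set \{0, 1, 2, 5, 8\} by default); P and F points from monotone
#' step tables, capped. When the protein-cap rule is enabled, P points are
#' withheld for foods whose baseline points exceed the configured threshold
#' unless V points reach the required minimum.
#'
#' @param panel A one-row tibble (or named list) with `protein_g` and
#'   `fiber_g` per 100 g/ml.
#' @param fvnl_pct The fvnl percentage (possibly imputed), or `NA` to score
#'   zero V points.
#' @param npsc_category Scoring category 1, 2 or 3.
#' @param tables An `npsc_point_tables` object.
#' @param baseline Baseline total, needed only by the protein-cap rule.
#' @return A list with integer components `v`, `p`, `f`.
#' @export
modifying_points <- function(panel, fvnl_pct, npsc_category = 2L,
                             tables = default_point_tables(),
                             baseline = NULL) {
  if (is.null(panel$protein_g) || is.na(panel$protein_g)) {
    abort("Modifying points require protein_g.",
          class = "foodswap_input_error")
  }
  fiber <- panel$fiber_g
  if (is.null(fiber) || is.na(fiber)) {
    abort("Modifying points require fiber_g (impute before scoring).",
          class = "foodswap_input_error")
  }
  v <- if (is.null(fvnl_pct) || is.na(fvnl_pct)) 0L else {
    v_points_from_pct(fvnl_pct, tables)
  }
  p <- step_points(panel$protein_g, tables$protein_g)
  f <- step_points(fiber, tables$fiber_g)

  rule <- tables$protein_cap_rule
  if (isTRUE(rule$enabled) && !is.null(baseline) &&
      baseline > rule$baseline_threshold && v < rule$v_required) {
    p <- 0L
  }
  list(v = v, p = p, f = f)
}

resolve_fvnl_pct <- function(record) {
  comp <- c(record[["pct_fvnl_nonconc"]], record[["pct_fvnl_conc"]],
            record[["pct_non_fvnl"]])
  if (length(comp) == 3 && !any(is.na(comp))) {
    if (all(comp == 0)) return(record[["fvnl_pct"]] %||% NA_real_)
    return(fvnl_percent(comp[1], comp[2], comp[3]))
  }
  record[["fvnl_pct"]] %||% NA_real_
}

#' Nutrient-profile score for one product
#'
#' Composes category determination, baseline points and modifying points
#' into the final score: `final = baseline - V - P - F`. Lower scores are
#' healthier; the switch engine ranks on this value. Fibre, calcium and
#' fvnl values must be present or already imputed (see
#' [impute_database()]); every field that was imputed rather than observed
#' is echoed in `imputed_inputs`.
#'
#' @param record A one-row record tibble.
#' @param db A `food_db` object supplying the category table.
#' @param tables An `npsc_point_tables` object.
#' @param imputed_fields Character vector naming fields of this record that
#'   were filled by imputation.
#' @return An `npsc_score` object.
#' @export
score_record <- function(record, db, tables = default_point_tables(),
                         imputed_fields = character()) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1L)
  categories <- if (inherits(db, "food_db")) db$categories else db
  npsc_category <- determine_category(record, categories)
  base <- baseline_points(record, npsc_category, tables)
  fvnl_pct <- resolve_fvnl_pct(record)
  mods <- modifying_points(record, fvnl_pct, npsc_category, tables,
                           baseline = base$total)
  structure(list(
    upc = record[["upc"]] %||% NA_character_,
    npsc_category = npsc_category,
    baseline = base,
    v_points = mods$v,
    p_points = mods$p,
    f_points = mods$f,
    final_score = base$total - mods$v - mods$p - mods$f,
    fvnl_pct = fvnl_pct,
    imputed_inputs = imputed_fields
  ), class = "npsc_score")
}

#' @export
print.npsc_score <- function(x, ...) {
  cat(sprintf("<npsc_score> %s (category %d)\n", x$upc, x$npsc_category))
  cat(sprintf("  baseline %d (energy %d + satfat %d + sugars %d + sodium %d)\n",
              x$baseline$total, x$baseline$energy, x$baseline$satfat,
              x$baseline$sugars, x$baseline$sodium))
  cat(sprintf("  modifying V %d, P %d, F %d\n",
              x$v_points, x$p_points, x$f_points))
  cat(sprintf("  final score %d (lower is healthier)\n", x$final_score))
  if (length(x$imputed_inputs)) {
    cat("  imputed:", paste(x$imputed_inputs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score every record in a database
#'
#' Applies imputation (unless already applied) and scores all records,
#' attaching a `scores` tibble to the database. A scored database is the
#' required input state of the switch engine.
#'
#' @param db A `food_db` object.
#' @param tables An `npsc_point_tables` object.
#' @param impute Run [impute_database()] first? Default `TRUE`.
#' @return The database with a `scores` element (one row per record: point
#'   breakdown, final score, and a semicolon-separated list of imputed
#'   fields), classed `scored_food_db`.
#' @export
score_database <- function(db, tables = default_point_tables(),
                           impute = TRUE) {
  stopifnot(inherits(db, "food_db"))
  imputed_by_upc <- list()
  if (impute) {
    imp <- impute_database(db)
    db <- imp$db
    if (nrow(imp$report)) {
      imputed_by_upc <- split(imp$report$field, imp$report$upc)
    }
  }
  records <- db$records
  n <- nrow(records)
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    sc <- score_record(rec, db, tables,
                       imputed_fields = imputed_by_upc[[rec$upc]] %||%
                         character())
    scores[[i]] <- tibble(
      upc = rec$upc,
      npsc_category = sc$npsc_category,
      energy_points = sc$baseline$energy,
      satfat_points = sc$baseline$satfat,
      sugars_points = sc$baseline$sugars,
      sodium_points = sc$baseline$sodium,
      baseline_points = sc$baseline$total,
      v_points = sc$v_points,
      p_points = sc$p_points,
      f_points = sc$f_points,
      final_score = sc$final_score,
      imputed = paste(sc$imputed_inputs, collapse = ";")
    )
  }
  db$scores <- if (n) dplyr::bind_rows(scores) else tibble(
    upc = character(), npsc_category = integer(), energy_points = integer(),
    satfat_points = integer(), sugars_points = integer(),
    sodium_points = integer(), baseline_points = integer(),
    v_points = integer(), p_points = integer(), f_points = integer(),
    final_score = integer(), imputed = character()
  )
  class(db) <- unique(c("scored_food_db", class(db)))
  db
}
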