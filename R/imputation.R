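#' Category-level means of observed fibre and calcium
#'
#' Arithmetic means over observed (non-absent) values only; absent values
#' are never counted as zero. Categories with no observations report an
#' undefined mean (`NA`) with a zero count.
#'
#' @param db A `food_db` object.
#' @return A tibble with one row per category: `category_id`, `fiber_mean`,
#'   `n_fiber_observed`, `calcium_mean`, `n_calcium_observed`.
#' @export
compute_category_stats <- function(db) {
  stopifnot(inherits(db, "food_db"))
  stats <- db$records |>
    group_by(.data$category_id) |>
    summarise(
      fiber_mean = if (any(!is.na(.data$fiber_g)))
        mean(.data$fiber_g, na.rm = TRUE) else NA_real_,
      n_fiber_observed = sum(!is.na(.data$fiber_g)),
      calcium_mean = if (any(!is.na(.data$calcium_mg)))
        mean(.data$calcium_mg, na.rm = TRUE) else NA_real_,
      n_calcium_observed = sum(!is.na(.data$calcium_mg)),
      .groups = "drop"
    )
  # categories with no records at all still get a (degenerate) row
  missing <- setdiff(db$categories$category_id, stats$category_id)
  if (length(missing)) {
    stats <- bind_rows(stats, tibble(
      category_id = missing, fiber_mean = NA_real_,
      n_fiber_observed = 0L, calcium_mean = NA_real_,
      n_calcium_observed = 0L
    ))
  }
  stats
}

impute_error <- function(field, category_id) {
  abort(sprintf(
    "Cannot impute %s for category '%s': no observed values and no category default.",
    field, category_id),
    class = "foodswap_imputation_error")
}

#' Impute missing fibre, calcium and fvnl values for one record
#'
#' Observed values pass through unchanged and unflagged. Missing fibre
#' becomes 0 in categories known not to contain fibre, otherwise the
#' category mean of observed values. Missing calcium is filled from the
#' category mean, but only for cheese categories (the only place the
#' scoring needs it). A missing fvnl composition resolves to 0 per cent in
#' categories without appreciable fruit-and-vegetable content, otherwise to
#' the category's configured default percentage.
#'
#' @param record A one-row record tibble.
#' @param category The record's one-row category tibble.
#' @param stats The record's category row from [compute_category_stats()].
#' @return A list with `record` (values filled in, including a resolved
#'   `fvnl_pct`) and `imputed`, a tibble of (`field`, `source`, `value`)
#'   rows for every field that was filled.
#' @export
impute_record <- function(record, category, stats) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1L, nrow(category) == 1L)
  filled <- tibble(field = character(), source = character(),
                   value = double())
  fill <- function(field, source, value) {
    filled <<- bind_rows(filled, tibble(field = field, source = source,
                                        value = value))
  }

  if (is.na(record$fiber_g)) {
    if (!isTRUE(category$fiber_possible)) {
      record$fiber_g <- 0
      fill("fiber_g", "zero-rule", 0)
    } else if (nrow(stats) == 1L && stats$n_fiber_observed >= 1L) {
      record$fiber_g <- stats$fiber_mean
      fill("fiber_g", "category-mean", stats$fiber_mean)
    } else {
      impute_error("fiber_g", category$category_id)
    }
  }

  if (is.na(record$calcium_mg) && isTRUE(category$is_cheese)) {
    if (nrow(stats) == 1L && stats$n_calcium_observed >= 1L) {
      record$calcium_mg <- stats$calcium_mean
      fill("calcium_mg", "category-mean", stats$calcium_mean)
    } else {
      impute_error("calcium_mg", category$category_id)
    }
  }

  comp <- c(record$pct_fvnl_nonconc, record$pct_fvnl_conc,
            record$pct_non_fvnl)
  has_composition <- !any(is.na(comp)) && any(comp > 0)
  has_pct <- !is.null(record[["fvnl_pct"]]) && !is.na(record[["fvnl_pct"]])
  if (!has_composition && !has_pct) {
    if (!isTRUE(category$fvnl_possible)) {
      record$fvnl_pct <- 0
      fill("fvnl_pct", "zero-rule", 0)
    } else if (!is.na(category$default_fvnl_pct)) {
      record$fvnl_pct <- category$default_fvnl_pct
      fill("fvnl_pct", "category-default", category$default_fvnl_pct)
    } else {
      impute_error("fvnl_pct", category$category_id)
    }
  }

  list(record = record, imputed = filled)
}

#' Impute missing values across a database
#'
#' Category statistics are computed once from the raw database and then
#' applied record by record; imputed values never feed back into the means.
#' The operation is idempotent: imputing an already-imputed database
#' changes nothing.
#'
#' @param db A `food_db` object.
#' @param stats Category statistics; defaults to
#'   [compute_category_stats()] on `db`.
#' @return A list with `db` (records filled in) and `report`, a tibble with
#'   one row per imputed field: `upc`, `field`, `source`
#'   (`zero-rule` / `category-mean` / `category-default`), `value`.
#' @export
impute_database <- function(db, stats = compute_category_stats(db)) {
  stopifnot(inherits(db, "food_db"))
  records <- db$records
  report <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    cat_row <- category_for(db, rec$category_id)
    st <- stats[stats$category_id == rec$category_id, ]
    out <- impute_record(rec, cat_row, st)
    records[i, ] <- out$record
    if (nrow(out$imputed)) {
      out$imputed$upc <- rec$upc
      report[[i]] <- out$imputed
    }
  }
  report <- bind_rows(report)
  if (nrow(report) == 0L) {
    report <- tibble(upc = character(), field = character(),
                     source = character(), value = double())
  } else {
    report <- report[, c("upc", "field", "source", "value")]
  }
  db$records <- records
  list(db = db, report = report)
}
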