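#' Recommend healthier same-category alternatives
#'
#' For a scanned product, lists products in the same category with a
#' strictly more favourable key, sorted best first: in `"npsc"` mode a
#' strictly lower final nutrient-profile score (ties broken by name then
#' barcode); in `"salt"` mode strictly lower sodium, tie-broken by final
#' score, then name, then barcode. For categories where like-for-like
#' switches are not offered (e.g. sugar-sweetened soft drinks), the
#' category's standard advisory message is returned instead and the
#' alternative list is empty.
#'
#' @param db A scored database (see [score_database()]).
#' @param upc Barcode of the query product.
#' @param mode `"npsc"` (overall profile) or `"salt"` (sodium-first).
#' @param max_results Maximum number of alternatives returned.
#' @return A `switch_result` object, or `NULL` when the barcode is unknown
#'   (the signal that routes to the crowdsourcing path).
#' @export
recommend <- function(db, upc, mode = c("npsc", "salt"), max_results = 10L) {
  mode <- match.arg(mode)
  if (!is_scored(db)) {
    abort("Database has not been scored; call score_database() first.",
          class = "foodswap_state_error")
  }
  query <- lookup_upc(db, upc)
  if (is.null(query)) return(NULL)

  cat_row <- category_for(db, query$category_id)
  if (isTRUE(cat_row$switch_excluded)) {
    return(new_switch_result(upc, mode, empty_alternatives(),
                             cat_row$standard_message))
  }

  pool <- db$records[db$records$category_id == query$category_id &
                       db$records$upc != upc, , drop = FALSE]
  pool <- left_join(pool, db$scores[, c("upc", "final_score")], by = "upc")
  query_score <- db$scores$final_score[db$scores$upc == upc]

  if (mode == "npsc") {
    better <- pool[pool$final_score < query_score, , drop = FALSE]
    better <- better[order(better$final_score, better$name, better$upc), ,
                     drop = FALSE]
  } else {
    better <- pool[pool$sodium_mg < query$sodium_mg, , drop = FALSE]
    better <- better[order(better$sodium_mg, better$final_score,
                           better$name, better$upc), , drop = FALSE]
  }
  better <- utils::head(better, max_results)

  alts <- if (nrow(better)) {
    labels <- lapply(seq_len(nrow(better)), function(i) {
      label_record(better[i, intersect(names(better), c(RECORD_COLUMNS, "fvnl_pct"))])
    })
    tibble(
      upc = better$upc, name = better$name, brand = better$brand,
      final_score = better$final_score, sodium_mg = better$sodium_mg,
      total_fat_color = vapply(labels, function(l) l$colors[["total_fat"]], ""),
      saturated_fat_color = vapply(labels, function(l) l$colors[["saturated_fat"]], ""),
      sugars_color = vapply(labels, function(l) l$colors[["sugars"]], ""),
      salt_color = vapply(labels, function(l) l$colors[["salt"]], "")
    )
  } else empty_alternatives()

  new_switch_result(upc, mode, alts, NA_character_)
}

empty_alternatives <- function() {
  tibble(upc = character(), name = character(), brand = character(),
         final_score = integer(), sodium_mg = double(),
         total_fat_color = character(), saturated_fat_color = character(),
         sugars_color = character(), salt_color = character())
}

new_switch_result <- function(upc, mode, alternatives, message) {
  structure(list(
    query_upc = upc, mode = mode, alternatives = alternatives,
    standard_message = if (is.na(message)) NULL else message
  ), class = "switch_result")
}

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf("<switch_result> %s (mode: %s)\n", x$query_upc, x$mode))
  if (!is.null(x$standard_message)) {
    cat(" ", x$standard_message, "\n")
  } else if (nrow(x$alternatives) == 0L) {
    cat("  no healthier alternative in this category\n")
  } else {
    print(x$alternatives[, c("upc", "name", "final_score", "sodium_mg")])
  }
  invisible(x)
}

#' Scan a barcode: label, score and switches in one call
#'
#' The primary pipeline: a known barcode yields the traffic-light label,
#' the nutrient-profile score and the healthier-switch result for the same
#' record; an unknown barcode yields a crowdsourcing prompt asking for
#' photographs of the front of pack, the nutrition information panel and
#' the ingredients list.
#'
#' @param db A scored database (see [score_database()]).
#' @param upc Barcode to scan.
#' @param mode Switch ranking mode, `"npsc"` or `"salt"`.
#' @param thresholds Traffic-light thresholds.
#' @param tables Point tables used when re-deriving the score breakdown.
#' @param max_results Maximum alternatives in the switch list.
#' @return A `scan_result` (elements `record`, `label`, `score`, `switch`)
#'   for a known barcode, or a `crowdsource_prompt` for an unknown one.
#' @export
scan_product <- function(db, upc, mode = c("npsc", "salt"),
                         thresholds = default_thresholds(),
                         tables = default_point_tables(),
                         max_results = 10L) {
  mode <- match.arg(mode)
  if (!is_scored(db)) {
    abort("Database has not been scored; call score_database() first.",
          class = "foodswap_state_error")
  }
  record <- lookup_upc(db, upc)
  if (is.null(record)) {
    return(structure(list(
      upc = upc,
      message = paste("Product not in database. Please photograph the",
                      "front of the package, the nutrition information",
                      "panel, and the ingredients list.")
    ), class = "crowdsource_prompt"))
  }
  imputed <- strsplit(db$scores$imputed[db$scores$upc == upc], ";")[[1]]
  list_res <- list(
    record = record,
    label = label_record(record, thresholds),
    score = score_record(record, db, tables,
                         imputed_fields = imputed[nzchar(imputed)]),
    switch = recommend(db, upc, mode, max_results)
  )
  structure(list_res, class = "scan_result")
}

#' @export
print.crowdsource_prompt <- function(x, ...) {
  cat(sprintf("<crowdsource_prompt> %s\n  %s\n", x$upc, x$message))
  invisible(x)
}

#' @export
print.scan_result <- function(x, ...) {
  print(x$label)
  print(x$score)
  print(x$switch)
  invisible(x)
}
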