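#' Convert sodium to salt equivalent
#'
#' Front-of-pack thresholds are expressed in grams of salt while nutrition
#' information panels declare sodium in milligrams. The standard conversion
#' `salt_g = sodium_mg * 2.5 / 1000` is applied before any salt
#' classification.
#'
#' @param sodium_mg Sodium in mg per 100 g/ml.
#' @return Salt in g per 100 g/ml.
#' @export
#' @examples
#' salt_from_sodium(600) # 1.5 g salt
salt_from_sodium <- function(sodium_mg) {
  sodium_mg * 2.5 / 1000
}

#' Validate a GTIN/UPC check digit
#'
#' Applies the GTIN mod-10 rule: digits are weighted 3,1,3,1,... from the
#' rightmost payload digit, and the check digit is the amount needed to reach
#' the next multiple of 10.
#'
#' @param upc A digit string of length 8, 12, 13 or 14.
#' @return `TRUE` if the final digit equals the mod-10 check digit of the
#'   preceding digits, `FALSE` otherwise.
#' @export
#' @examples
#' validate_check_digit("036000291452") # TRUE
#' validate_check_digit("036000291453") # FALSE
validate_check_digit <- function(upc) {
  stopifnot(is.character(upc), length(upc) == 1L)
  if (!grepl("^[0-9]+$", upc)) {
    abort("`upc` must contain digits only.", class = "foodswap_input_error")
  }
  if (!nchar(upc) %in% c(8L, 12L, 13L, 14L)) {
    abort(
      sprintf("Unsupported barcode length %d (expected 8, 12, 13 or 14).",
              nchar(upc)),
      class = "foodswap_input_error"
    )
  }
  digits <- as.integer(strsplit(upc, "")[[1]])
  n <- length(digits)
  payload <- rev(digits[-n])
  weights <- rep(c(3L, 1L), length.out = length(payload))
  check <- (10L - sum(payload * weights) %% 10L) %% 10L
  digits[n] == check
}

gtin_check_digit <- function(payload) {
  digits <- as.integer(strsplit(payload, "")[[1]])
  weights <- rep(c(3L, 1L), length.out = length(digits))
  (10L - sum(rev(digits) * weights) %% 10L) %% 10L
}

empty_records <- function() {
  tibble(
    upc = character(), name = character(), brand = character(),
    category_id = character(), is_beverage = logical(),
    serving_size_g = double(),
    energy_kj = double(), protein_g = double(), total_fat_g = double(),
    saturated_fat_g = double(), carbohydrate_g = double(),
    sugars_g = double(), sodium_mg = double(), fiber_g = double(),
    calcium_mg = double(), pct_fvnl_nonconc = double(),
    pct_fvnl_conc = double(), pct_non_fvnl = double(),
    provenance = character()
  )
}

empty_categories <- function() {
  tibble(
    category_id = character(), name = character(), is_beverage = logical(),
    fiber_possible = logical(), fvnl_possible = logical(),
    default_fvnl_pct = double(), npsc_category3_member = logical(),
    is_cheese = logical(), switch_excluded = logical(),
    standard_message = character()
  )
}

coerce_records <- function(records) {
  records <- as_tibble(records)
  if (!"brand" %in% names(records)) records$brand <- NA_character_
  if (!"provenance" %in% names(records)) records$provenance <- "surveyed"
  if (!"fvnl_pct" %in% names(records)) records$fvnl_pct <- NA_real_
  for (col in setdiff(RECORD_COLUMNS, names(records))) {
    records[[col]] <- if (col == "is_beverage") NA else NA_real_
  }
  chr_cols <- c("upc", "name", "brand", "category_id", "provenance")
  for (col in chr_cols) records[[col]] <- as.character(records[[col]])
  num_cols <- setdiff(RECORD_COLUMNS, c(chr_cols, "is_beverage"))
  for (col in num_cols) records[[col]] <- as.numeric(records[[col]])
  records$is_beverage <- as.logical(records$is_beverage)
  records[, c(RECORD_COLUMNS, "fvnl_pct")]
}

coerce_categories <- function(categories) {
  categories <- as_tibble(categories)
  if (!"is_cheese" %in% names(categories)) categories$is_cheese <- FALSE
  for (col in setdiff(CATEGORY_COLUMNS, names(categories))) {
    categories[[col]] <- switch(col,
      default_fvnl_pct = NA_real_,
      standard_message = NA_character_,
      FALSE
    )
  }
  lgl_cols <- c("is_beverage", "fiber_possible", "fvnl_possible",
                "npsc_category3_member", "is_cheese", "switch_excluded")
  for (col in lgl_cols) {
    categories[[col]] <- as.logical(categories[[col]])
    categories[[col]][is.na(categories[[col]])] <- FALSE
  }
  categories$category_id <- as.character(categories$category_id)
  categories$name <- as.character(categories$name)
  categories$standard_message <- as.character(categories$standard_message)
  categories$default_fvnl_pct <- as.numeric(categories$default_fvnl_pct)
  categories[, CATEGORY_COLUMNS]
}

validate_record_rows <- function(records, categories) {
  problems <- character()
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
    }
  }
  bad_upc <- which(is.na(records$upc) | !grepl("^[0-9]+$", records$upc))
  note(bad_upc, "upc must be a non-empty digit string")

  dup <- records$upc[duplicated(records$upc) & !is.na(records$upc)]
  for (u in unique(dup)) {
    rows <- which(records$upc == u)
    problems <- c(problems, sprintf(
      "duplicate upc '%s' on rows %s", u, paste(rows, collapse = ", ")))
  }

  unknown <- which(!records$category_id %in% categories$category_id)
  note(unknown, sprintf("unknown category_id '%s'",
                        records$category_id[unknown]))

  for (col in REQUIRED_NUTRIENTS) {
    note(which(is.na(records[[col]])), sprintf("missing required %s", col))
  }
  num_cols <- c(REQUIRED_NUTRIENTS, "fiber_g", "calcium_mg",
                "serving_size_g", "pct_fvnl_nonconc", "pct_fvnl_conc",
                "pct_non_fvnl")
  for (col in num_cols) {
    note(which(!is.na(records[[col]]) & records[[col]] < 0),
         sprintf("negative %s", col))
  }
  note(which(!is.na(records$saturated_fat_g) & !is.na(records$total_fat_g) &
               records$saturated_fat_g > records$total_fat_g),
       "saturated_fat_g exceeds total_fat_g")
  note(which(!is.na(records$sugars_g) & !is.na(records$carbohydrate_g) &
               records$sugars_g > records$carbohydrate_g),
       "sugars_g exceeds carbohydrate_g")
  for (col in c("pct_fvnl_nonconc", "pct_fvnl_conc", "pct_non_fvnl")) {
    note(which(!is.na(records[[col]]) & records[[col]] > 100),
         sprintf("%s above 100", col))
  }
  note(which(!is.na(records$provenance) &
               !records$provenance %in% c("surveyed", "crowdsourced")),
       "provenance must be 'surveyed' or 'crowdsourced'")
  problems
}

validate_category_rows <- function(categories) {
  problems <- character()
  dup <- unique(categories$category_id[duplicated(categories$category_id)])
  if (length(dup)) {
    problems <- c(problems,
                  sprintf("duplicate category_id '%s'", dup))
  }
  bad_msg <- which(categories$switch_excluded &
                     (is.na(categories$standard_message) |
                        !nzchar(categories$standard_message)))
  if (length(bad_msg)) {
    problems <- c(problems, sprintf(
      "category '%s': switch_excluded requires a standard_message",
      categories$category_id[bad_msg]))
  }
  bad_dflt <- which(!is.na(categories$default_fvnl_pct) &
                      !categories$fvnl_possible)
  if (length(bad_dflt)) {
    problems <- c(problems, sprintf(
      "category '%s': default_fvnl_pct set but fvnl_possible is FALSE",
      categories$category_id[bad_dflt]))
  }
  bad_rng <- which(!is.na(categories$default_fvnl_pct) &
                     (categories$default_fvnl_pct < 0 |
                        categories$default_fvnl_pct > 100))
  if (length(bad_rng)) {
    problems <- c(problems, sprintf(
      "category '%s': default_fvnl_pct outside [0, 100]",
      categories$category_id[bad_rng]))
  }
  problems
}

#' Construct a validated food database
#'
#' Bundles a branded-food record table (one row per SKU, nutrients per
#' 100 g for foods and per 100 ml for beverages) with its category table,
#' and enforces all structural invariants: digit-only unique barcodes,
#' resolvable categories, non-negative nutrients, saturated fat not above
#' total fat, sugars not above carbohydrate, and excluded categories
#' carrying a standard advisory message. Optional nutrients are `NA` when
#' absent; absence is never conflated with zero.
#'
#' @param records A data frame of product records (see [load_database()] for
#'   the column schema).
#' @param categories A data frame of category definitions.
#' @param strict_checksum If `TRUE`, barcodes of standard GTIN length with a
#'   failing mod-10 check digit are an error; by default they only warn,
#'   since real-world crowdsourced barcodes sometimes fail the checksum.
#' @return An object of class `food_db` with elements `records` and
#'   `categories`.
#' @export
food_database <- function(records = empty_records(),
                          categories = empty_categories(),
                          strict_checksum = FALSE) {
  records <- coerce_records(records)
  categories <- coerce_categories(categories)

  # records inherit the category's beverage flag unless explicitly set
  cat_bev <- setNames(categories$is_beverage, categories$category_id)
  missing_bev <- is.na(records$is_beverage)
  records$is_beverage[missing_bev] <-
    unname(cat_bev[records$category_id[missing_bev]])

  problems <- c(validate_category_rows(categories),
                validate_record_rows(records, categories))
  if (length(problems)) {
    abort(c("Invalid food database:", setNames(problems, rep("x", length(problems)))),
          class = "foodswap_validation_error")
  }

  std_len <- nchar(records$upc) %in% c(8L, 12L, 13L, 14L)
  bad_check <- records$upc[std_len][
    !vapply(records$upc[std_len], validate_check_digit, logical(1))]
  if (length(bad_check)) {
    msg <- sprintf("%d barcode(s) fail the GTIN mod-10 check digit: %s",
                   length(bad_check),
                   paste(utils::head(bad_check, 5), collapse = ", "))
    if (strict_checksum) {
      abort(msg, class = "foodswap_validation_error")
    }
    warn(msg, class = "foodswap_checksum_warning")
  }

  structure(list(records = records, categories = categories),
            class = "food_db")
}

#' @export
print.food_db <- function(x, ...) {
  n_bev <- sum(x$records$is_beverage)
  cat(sprintf("<food_db> %d records in %d categories (%d beverages)\n",
              nrow(x$records), nrow(x$categories), n_bev))
  if (!is.null(x$scores)) {
    cat(sprintf("  scored: %d nutrient-profile scores attached\n",
                nrow(x$scores)))
  }
  invisible(x)
}

is_scored <- function(db) {
  inherits(db, "food_db") && !is.null(db$scores)
}

read_table_file <- function(path, what = c("records", "categories")) {
  what <- match.arg(what)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "foodswap_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::fromJSON(path)
    if (is.list(out) && !is.data.frame(out) && what %in% names(out)) {
      out <- out[[what]]
    }
    if (length(out) == 0) {
      out <- if (what == "records") empty_records() else empty_categories()
    }
    as_tibble(out)
  } else {
    # empty cell means absent -- distinct from a literal 0
    classes <- if (what == "records") c(upc = "character") else NA
    as_tibble(read.csv(path, colClasses = classes, na.strings = "",
                       stringsAsFactors = FALSE, check.names = FALSE))
  }
}

#' Load a food database from disk
#'
#' Reads the record and category tables from CSV (UTF-8, comma-separated,
#' header row; empty cells are absent values, distinct from `"0"`) or JSON,
#' then validates the assembled database. Rows violating an invariant are
#' rejected with row-level diagnostics.
#'
#' The records table has columns `upc, name, brand, category_id,
#' is_beverage, serving_size_g, energy_kj, protein_g, total_fat_g,
#' saturated_fat_g, carbohydrate_g, sugars_g, sodium_mg, fiber_g,
#' calcium_mg, pct_fvnl_nonconc, pct_fvnl_conc, pct_non_fvnl, provenance`;
#' the category table has `category_id, name, is_beverage, fiber_possible,
#' fvnl_possible, default_fvnl_pct, npsc_category3_member, is_cheese,
#' switch_excluded, standard_message`.
#'
#' @param records_path Path to the records CSV/JSON, or to a combined JSON
#'   file with `records` and `categories` members.
#' @param categories_path Path to the category CSV/JSON. May be omitted for
#'   a combined JSON file.
#' @param strict_checksum Passed to [food_database()].
#' @return A validated `food_db` object.
#' @export
load_database <- function(records_path, categories_path = NULL,
                          strict_checksum = FALSE) {
  if (is.null(categories_path)) {
    if (!grepl("\\.json$", records_path, ignore.case = TRUE)) {
      abort("`categories_path` is required unless loading a combined JSON file.",
            class = "foodswap_io_error")
    }
    categories_path <- records_path
  }
  records <- read_table_file(records_path, "records")
  categories <- read_table_file(categories_path, "categories")
  food_database(records, categories, strict_checksum = strict_checksum)
}

#' Save a food database to disk
#'
#' Writing then reloading reproduces an equal database field-for-field,
#' including the distinction between absent and zero optional nutrients
#' (absent values are written as empty CSV cells or JSON `null`).
#'
#' @param db A `food_db` object.
#' @param path For `format = "csv"`, a directory into which `records.csv`
#'   and `categories.csv` are written; for `format = "json"`, a single file
#'   path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
save_database <- function(db, path, format = c("csv", "json")) {
  stopifnot(inherits(db, "food_db"))
  format <- match.arg(format)
  records <- db$records[, RECORD_COLUMNS]
  categories <- db$categories[, CATEGORY_COLUMNS]
  if (format == "csv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    rp <- file.path(path, "records.csv")
    cp <- file.path(path, "categories.csv")
    write.csv(records, rp, row.names = FALSE, na = "")
    write.csv(categories, cp, row.names = FALSE, na = "")
    invisible(c(records = rp, categories = cp))
  } else {
    jsonlite::write_json(
      list(records = records, categories = categories),
      path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
    )
    invisible(c(combined = path))
  }
}

#' Look up a product by barcode
#'
#' Exact-match lookup on the UPC key. An unknown barcode is not an error:
#' it returns `NULL`, the signal that routes a scan to the crowdsourcing
#' path.
#'
#' @param db A `food_db` object.
#' @param upc A digit-string barcode.
#' @return The matching one-row record tibble, or `NULL` if the barcode is
#'   not in the database.
#' @export
lookup_upc <- function(db, upc) {
  stopifnot(inherits(db, "food_db"))
  if (!is.character(upc) || length(upc) != 1L || !grepl("^[0-9]+$", upc)) {
    abort("`upc` must be a single digit-only string.",
          class = "foodswap_input_error")
  }
  hit <- db$records[db$records$upc == upc, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit
}

category_for <- function(db, category_id) {
  db$categories[db$categories$category_id == category_id, , drop = FALSE]
}
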