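PHOTO_SLOTS <- c("front_of_pack", "nip", "ingredients")

#' Create an empty crowdsourcing submission queue
#'
#' Submissions capture barcodes scanned but not found in the database,
#' together with the three labelled photograph references (front of pack,
#' nutrition information panel, ingredients list) a user supplies. A
#' submission moves `pending` -> `entered` (once a data-entry operator has
#' transcribed the photographs into a full record) -> `merged`.
#'
#' @return A `submission_queue` tibble.
#' @export
submission_queue <- function() {
  structure(tibble(
    upc = character(),
    photo_front_of_pack = character(),
    photo_nip = character(),
    photo_ingredients = character(),
    submitted_at = as.POSIXct(character(), tz = "UTC"),
    status = character(),
    entered_record = list()
  ), class = c("submission_queue", class(tibble())))
}

#' Queue a submission for a barcode missing from the database
#'
#' Appends a pending submission. Repeat scans of the same unknown barcode
#' are coalesced into one pending submission, with photograph references
#' unioned slot by slot. A barcode already present in the database is
#' rejected.
#'
#' @param queue A `submission_queue`.
#' @param db The current `food_db` (to reject known barcodes).
#' @param upc The scanned digit-string barcode.
#' @param photos Named character vector of photo references; names among
#'   `front_of_pack`, `nip`, `ingredients`. Slots are labelled and
#'   order-independent; missing slots stay empty until a later scan fills
#'   them.
#' @param submitted_at Submission timestamp.
#' @return The updated queue.
#' @export
record_missing_scan <- function(queue, db, upc, photos = character(),
                                submitted_at = Sys.time()) {
  stopifnot(inherits(queue, "submission_queue"))
  if (!grepl("^[0-9]+$", upc)) {
    abort("`upc` must be a digit-only string.",
          class = "foodswap_input_error")
  }
  if (!is.null(lookup_upc(db, upc))) {
    abort(sprintf("Barcode %s is already in the database; nothing to crowdsource.",
                  upc),
          class = "foodswap_submission_rejected")
  }
  bad <- setdiff(names(photos), PHOTO_SLOTS)
  if (length(bad)) {
    abort(sprintf("Unknown photo slot(s): %s.", paste(bad, collapse = ", ")),
          class = "foodswap_input_error")
  }
  slot <- function(nm) if (nm %in% names(photos)) photos[[nm]] else NA_character_

  existing <- which(queue$upc == upc & queue$status == "pending")
  if (length(existing)) {
    i <- existing[1]
    for (nm in PHOTO_SLOTS) {
      col <- paste0("photo_", nm)
      if (is.na(queue[[col]][i]) && !is.na(slot(nm))) {
        queue[[col]][i] <- slot(nm)
      }
    }
    return(queue)
  }
  new_row <- tibble(
    upc = upc,
    photo_front_of_pack = slot("front_of_pack"),
    photo_nip = slot("nip"),
    photo_ingredients = slot("ingredients"),
    submitted_at = as.POSIXct(submitted_at, tz = "UTC"),
    status = "pending",
    entered_record = list(NULL)
  )
  out <- bind_rows(queue, new_row)
  class(out) <- class(queue)
  out
}

#' Attach a transcribed record to a pending submission
#'
#' Models the manual data-entry step: an operator reads the submitted
#' photographs and types up the product record. The record is validated
#' against the panel invariants before the submission advances to
#' `entered`.
#'
#' @param queue A `submission_queue`.
#' @param db The current `food_db` (for category validation).
#' @param upc The pending submission's barcode.
#' @param record A one-row record tibble for that barcode.
#' @return The updated queue.
#' @export
enter_submission <- function(queue, db, upc, record) {
  stopifnot(inherits(queue, "submission_queue"))
  i <- which(queue$upc == upc & queue$status == "pending")
  if (!length(i)) {
    abort(sprintf("No pending submission for barcode %s.", upc),
          class = "foodswap_input_error")
  }
  record <- coerce_records(record)
  if (record$upc != upc) {
    abort("Entered record's upc does not match the submission.",
          class = "foodswap_input_error")
  }
  record$provenance <- "crowdsourced"
  problems <- validate_record_rows(record, db$categories)
  if (length(problems)) {
    abort(c("Entered record is invalid:",
            setNames(problems, rep("x", length(problems)))),
          class = "foodswap_validation_error")
  }
  queue$entered_record[[i[1]]] <- record
  queue$status[i[1]] <- "entered"
  queue
}

#' Merge entered submissions into a new database release
#'
#' Adds every `entered` record whose barcode is not already in the
#' database and advances it to `merged`; a colliding barcode is skipped
#' and reported, never silently overwritten. Merging is idempotent:
#' merging the same queue twice equals merging once.
#'
#' @param db A `food_db` object.
#' @param queue A `submission_queue` with entered submissions.
#' @return A list with `db` (the new release), `queue` (statuses
#'   advanced) and `report` (counts and skipped barcodes).
#' @export
merge_submissions <- function(db, queue) {
  stopifnot(inherits(db, "food_db"), inherits(queue, "submission_queue"))
  entered <- which(queue$status == "entered")
  added <- 0L
  skipped <- character()
  new_records <- list()
  seen <- db$records$upc
  for (i in entered) {
    rec <- queue$entered_record[[i]]
    if (rec$upc %in% seen) {
      skipped <- c(skipped, rec$upc)
      next
    }
    new_records[[length(new_records) + 1L]] <- rec
    seen <- c(seen, rec$upc)
    queue$status[i] <- "merged"
    added <- added + 1L
  }
  if (added) {
    db <- food_database(bind_rows(db$records, bind_rows(new_records)),
                       db$categories)
  }
  list(db = db, queue = queue,
       report = list(added = added, skipped = length(skipped),
                     skipped_upcs = skipped))
}

#' Persist or restore a submission queue as JSON lines
#'
#' @param queue A `submission_queue`.
#' @param path File path for the JSON-lines representation.
#' @return `write_queue` returns the path invisibly; `read_queue` the
#'   restored queue.
#' @export
write_queue <- function(queue, path) {
  stopifnot(inherits(queue, "submission_queue"))
  lines <- vapply(seq_len(nrow(queue)), function(i) {
    jsonlite::toJSON(list(
      upc = queue$upc[i],
      photos = list(
        front_of_pack = queue$photo_front_of_pack[i],
        nip = queue$photo_nip[i],
        ingredients = queue$photo_ingredients[i]
      ),
      submitted_at = format(queue$submitted_at[i], "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC"),
      status = queue$status[i],
      entered_record = queue$entered_record[[i]]
    ), auto_unbox = TRUE, na = "null", digits = NA, dataframe = "rows")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_queue
#' @export
read_queue <- function(path) {
  queue <- submission_queue()
  for (line in readLines(path)) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    rec <- if (is.null(x$entered_record) || length(x$entered_record) == 0) {
      list(NULL)
    } else {
      list(coerce_records(as_tibble(x$entered_record)))
    }
    row <- tibble(
      upc = x$upc,
      photo_front_of_pack = x$photos$front_of_pack %||% NA_character_,
      photo_nip = x$photos$nip %||% NA_character_,
      photo_ingredients = x$photos$ingredients %||% NA_character_,
      submitted_at = as.POSIXct(x$submitted_at, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ"),
      status = x$status,
      entered_record = rec
    )
    out <- bind_rows(queue, row)
    class(out) <- class(queue)
    queue <- out
  }
  queue
}
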