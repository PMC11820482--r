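# Respondent data model: the codebook declares every column of a response
# table (semantic type, allowed levels, range, units) and drives validation.

WBQ_EXCLUSION_FLAGS <- c("excl_pregnancy", "excl_breastfeeding", "excl_uti",
                         "excl_diabetes", "excl_kidney_disease",
                         "excl_medication", "excl_recent_symptoms")

#' Build the WBQ codebook
#'
#' One row per column of a response table. Semantic types:
#' `id`, `categorical`, `ordinal` (integer range), `binary` (yes/no),
#' `numeric`, `frequency` (the 6-level consumption scale). The
#' food-frequency section is configurable: pass the item identifiers of your
#' composition table (columns are named `food_<item>`).
#'
#' @param food_items character vector of food item ids
#'   (default: items of [default_composition()]).
#' @return data.frame of class `wbq_codebook` with columns
#'   `name`, `type`, `levels` (";"-separated), `min`, `max`, `units`, `required`.
#' @export
wbq_codebook <- function(food_items = default_composition()$item) {
  row <- function(name, type, levels = NA_character_, min = NA_real_,
                  max = NA_real_, units = NA_character_, required = TRUE) {
    data.frame(name = name, type = type, levels = levels, min = min, max = max,
               units = units, required = required, stringsAsFactors = FALSE)
  }
  cb <- rbind(
    row("id", "id"),
    row("gender", "categorical", "male;female"),
    row("age", "numeric", min = 0, max = 120, units = "years"),
    row("weight_kg", "numeric", min = 0, max = 400, units = "kg"),
    row("height_m", "numeric", min = 0, max = 2.6, units = "m"),
    row("education_years", "numeric", min = 0, max = 40, units = "years"),
    row("residence", "categorical", "capital;other_city;small_town;village"),
    row("family_status", "categorical", "unmarried;married;divorced"),
    row("profession", "categorical", "self_employed;private;public;other"),
    row("work_hours_week", "numeric", min = 0, max = 120, units = "hours/week"),
    row("labor_intensity", "ordinal", min = 1, max = 5),
    row("physical_strain", "ordinal", min = 1, max = 5),
    row("mental_strain", "ordinal", min = 1, max = 5),
    row("wc_access", "ordinal", min = 1, max = 5),
    row("weather_exposure", "ordinal", min = 1, max = 5),
    row("water_access", "ordinal", min = 1, max = 5),
    row("bottle_at_work", "binary", "yes;no"),
    row("bottle_during_day", "binary", "yes;no"),
    row("glass_during_day", "binary", "yes;no"),
    row("water_without_thirst", "binary", "yes;no"),
    row("water_for_pleasure", "binary", "yes;no"),
    do.call(rbind, lapply(paste0("bev_", WBQ_BEVERAGES), row, type = "frequency")),
    do.call(rbind, lapply(paste0("food_", food_items), row, type = "frequency")),
    row("drinking_water_ml", "numeric", min = 0, max = 20000, units = "mL/day"),
    row("urination_scale", "ordinal", min = 1, max = 5),
    row("defecation_scale", "ordinal", min = 1, max = 5),
    row("sweat_rest_scale", "ordinal", min = 1, max = 10),
    row("sweat_exercise_scale", "ordinal", min = 1, max = 10),
    row("ipaq_vigorous_days", "ordinal", min = 0, max = 7, units = "days/week"),
    row("ipaq_vigorous_min", "numeric", min = 0, max = 1440, units = "min/session"),
    row("ipaq_moderate_days", "ordinal", min = 0, max = 7, units = "days/week"),
    row("ipaq_moderate_min", "numeric", min = 0, max = 1440, units = "min/session"),
    row("ipaq_walking_days", "ordinal", min = 0, max = 7, units = "days/week"),
    row("ipaq_walking_min", "numeric", min = 0, max = 1440, units = "min/session"),
    do.call(rbind, lapply(WBQ_EXCLUSION_FLAGS, row, type = "binary",
                          levels = "yes;no", required = FALSE))
  )
  if (anyDuplicated(cb$name)) stop("duplicated column name in codebook")
  class(cb) <- c("wbq_codebook", "data.frame")
  cb
}

#' Read / write a codebook as JSON
#' @param path file path.
#' @return For `read_codebook`, a `wbq_codebook` data.frame.
#' @export
read_codebook <- function(path) {
  cb <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  need <- c("name", "type", "levels", "min", "max", "units", "required")
  if (!all(need %in% names(cb))) stop("codebook document missing fields")
  if (anyDuplicated(cb$name)) stop("duplicated column name in codebook")
  class(cb) <- c("wbq_codebook", "data.frame")
  cb
}

#' @rdname read_codebook
#' @param codebook a `wbq_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(as.data.frame(codebook), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

codebook_levels <- function(cb_row) strsplit(cb_row$levels, ";", fixed = TRUE)[[1]]

# Values accepted as explicit missing markers in a raw CSV cell.
MISSING_TOKENS <- c("", "NA")

#' Read and validate a WBQ response table
#'
#' Reads a UTF-8 comma-separated response file (header row, one row per
#' respondent) and validates every cell against the codebook. Out-of-range
#' ordinals, unknown category levels and unparsable numbers are *not* silently
#' coerced: they become `NA` in the returned table and a validation-error
#' record naming the row, column and offending value. Empty cells and "NA"
#' are explicit missing markers.
#'
#' @param path CSV file path.
#' @param codebook a `wbq_codebook` (default [wbq_codebook()]).
#' @return data.frame with typed columns, with attributes
#'   `validation_errors` (data.frame row/column/value/message) and `codebook`.
#' @export
read_responses <- function(path, codebook = wbq_codebook()) {
  if (!file.exists(path)) stop("cannot read responses: file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, stringsAsFactors = FALSE)
  required <- codebook$name[codebook$required]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("response table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_responses(raw, codebook)
}

#' Validate an already-loaded character response table
#' @param raw data.frame of character columns.
#' @inheritParams read_responses
#' @return as [read_responses()].
#' @export
validate_responses <- function(raw, codebook = wbq_codebook()) {
  errs <- list()
  note <- function(rows, col, vals, msg) {
    if (!length(rows)) return()
    errs[[length(errs) + 1L]] <<- data.frame(
      row = rows, column = col, value = vals, message = msg,
      stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(codebook))) {
    cbr <- codebook[i, ]
    nm <- cbr$name
    if (!nm %in% names(raw)) {
      if (cbr$required) stop("missing mandatory column: ", nm)
      next
    }
    x <- trimws(raw[[nm]])
    miss <- x %in% MISSING_TOKENS | is.na(x)
    val <- rep(NA, length(x))
    switch(cbr$type,
      id = { val <- x; val[miss] <- NA_character_ },
      numeric = {
        num <- suppressWarnings(as.numeric(x))
        bad <- !miss & is.na(num)
        note(which(bad), nm, x[bad], "not a number")
        oob <- !miss & !is.na(num) &
          ((!is.na(cbr$min) & num < cbr$min) | (!is.na(cbr$max) & num > cbr$max))
        note(which(oob), nm, x[oob],
             sprintf("out of range [%s, %s]", cbr$min, cbr$max))
        num[oob | miss] <- NA_real_
        val <- num
      },
      ordinal = {
        num <- suppressWarnings(as.numeric(x))
        bad <- !miss & (is.na(num) | num != round(num))
        note(which(bad), nm, x[bad], "not an integer scale value")
        oob <- !miss & !bad & (num < cbr$min | num > cbr$max)
        note(which(oob), nm, x[oob],
             sprintf("outside scale %d-%d", as.integer(cbr$min), as.integer(cbr$max)))
        num[miss | bad | oob] <- NA_real_
        val <- as.integer(num)
      },
      categorical = {
        lv <- codebook_levels(cbr)
        low <- tolower(x)
        bad <- !miss & !(low %in% lv)
        note(which(bad), nm, x[bad],
             paste0("unknown level (allowed: ", paste(lv, collapse = ", "), ")"))
        low[miss | bad] <- NA_character_
        val <- low
      },
      binary = {
        low <- tolower(x)
        low[low %in% c("1", "true")] <- "yes"
        low[low %in% c("0", "false")] <- "no"
        bad <- !miss & !(low %in% c("yes", "no"))
        note(which(bad), nm, x[bad], "not a yes/no value")
        low[miss | bad] <- NA_character_
        val <- low
      },
      frequency = {
        canon <- canonical_frequency_label(x)
        bad <- !miss & is.na(canon)
        note(which(bad), nm, x[bad], "unknown frequency category")
        canon[miss] <- NA_character_
        val <- canon
      },
      stop("unknown codebook type: ", cbr$type)
    )
    out[[nm]] <- val
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  verrs <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(), column = character(), value = character(),
               message = character(), stringsAsFactors = FALSE)
  attr(res, "validation_errors") <- verrs
  attr(res, "codebook") <- codebook
  res
}

#' Write a response table back to CSV
#'
#' Inverse of [read_responses()]: numeric columns are written with 17
#' significant digits so that a read/write round trip is exact.
#'
#' @param data typed response data.frame.
#' @param path output CSV path.
#' @export
write_responses <- function(data, path) {
  fmt <- data
  for (nm in names(fmt)) {
    if (is.numeric(fmt[[nm]])) {
      s <- vapply(fmt[[nm]], function(v)
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g"), "")
      fmt[[nm]] <- s
    } else {
      fmt[[nm]] <- ifelse(is.na(fmt[[nm]]), "", as.character(fmt[[nm]]))
    }
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Apply the study's exclusion criteria
#'
#' A respondent is dropped iff any exclusion flag is "yes" or age lies outside
#' the inclusive 18-65 band. Missing flags are treated as "no" (the original
#' form enforced them at entry) and this assumption is recorded in the log.
#' Missing age does not trigger exclusion.
#'
#' @param data typed response data.frame (as from [read_responses()]).
#' @param flags character vector of exclusion flag columns
#'   (default: all `excl_*` flags of the codebook).
#' @param age_range inclusive age bounds, default `c(18, 65)`.
#' @return list with `retained` (data.frame), `excluded` (data.frame) and
#'   `log` (data.frame id/reason, plus an `assumptions` attribute listing flags
#'   that were absent and defaulted to "no").
#' @export
exclusion_filter <- function(data, flags = WBQ_EXCLUSION_FLAGS,
                             age_range = c(18, 65)) {
  n <- nrow(data)
  reasons <- vector("list", n)
  assumed <- character()
  for (fl in flags) {
    if (!fl %in% names(data)) {
      assumed <- c(assumed, fl)
      next
    }
    hit <- !is.na(data[[fl]]) & data[[fl]] == "yes"
    for (i in which(hit)) reasons[[i]] <- c(reasons[[i]], fl)
  }
  if ("age" %in% names(data)) {
    age <- data$age
    bad_age <- !is.na(age) & (age < age_range[1] | age > age_range[2])
    for (i in which(bad_age)) reasons[[i]] <- c(reasons[[i]], "age")
  }
  drop <- lengths(reasons) > 0L
  log <- data.frame(
    id = as.character(data$id[drop]),
    reason = vapply(reasons[drop], paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  attr(log, "assumptions") <- if (length(assumed))
    paste0("flag(s) absent, treated as 'no': ", paste(assumed, collapse = ", "))
    else character()
  list(retained = data[!drop, , drop = FALSE],
       excluded = data[drop, , drop = FALSE],
       log = log)
}
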