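#' @keywords internal
"_PACKAGE"

# Canonical order of the six consumption-frequency categories used throughout
# the questionnaire (beverages and foods share the same scale).
WBQ_FREQ_LEVELS <- c("never/rarely", "1-2 times per week", "3-6 times per week",
                     "1-2 times per day", "3-4 times per day", ">5 times per day")

# The five beverage categories of the instrument.
WBQ_BEVERAGES <- c("juices_soda", "coffee_milk", "milkshake_granita", "tea", "alcohol")

#' Default frequency-to-times/day recoding
#'
#' The six ordinal consumption categories are mapped to mean daily frequencies:
#' never/rarely -> 0, 1-2 times per week -> 0.066, 3-6 times per week -> 0.214,
#' 1-2 times per day -> 0.643, 3-4 times per day -> 1, >5 times per day -> 2.5.
#' These constants turn the 6-point Likert frequency scale into a continuous
#' exposure (times/day). Note the published "3-4 times per day" value is 1
#' time/day, which breaks the midpoint pattern; it is used verbatim.
#'
#' @return Named numeric vector of length 6, named by category label.
#' @export
#' @examples
#' default_frequency_recode()[["1-2 times per day"]]
default_frequency_recode <- function() {
  stats::setNames(c(0, 0.066, 0.214, 0.643, 1, 2.5), WBQ_FREQ_LEVELS)
}

#' Canonicalize a frequency category label
#'
#' Accepts minor lexical variants of the six category labels (en dashes,
#' "times/week" shorthand, surrounding whitespace, case) and returns the
#' canonical label. Unknown labels return `NA_character_`.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels (NA where unrecognized).
#' @export
canonical_frequency_label <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("–|—", "-", key)          # en/em dash -> hyphen
  key <- gsub("\\s+", " ", key)
  alias <- c(
    "never/rarely" = "never/rarely",
    "never" = "never/rarely",
    "rarely" = "never/rarely",
    "1-2 times per week" = "1-2 times per week",
    "1-2/week" = "1-2 times per week",
    "1-2 times a week" = "1-2 times per week",
    "3-6 times per week" = "3-6 times per week",
    "3-6/week" = "3-6 times per week",
    "3-6 times a week" = "3-6 times per week",
    "1-2 times per day" = "1-2 times per day",
    "1-2/day" = "1-2 times per day",
    "1-2 times a day" = "1-2 times per day",
    "3-4 times per day" = "3-4 times per day",
    "3-4/day" = "3-4 times per day",
    "3-4 times a day" = "3-4 times per day",
    ">5 times per day" = ">5 times per day",
    ">5/day" = ">5 times per day",
    "more than 5 times per day" = ">5 times per day"
  )
  out <- unname(alias[key])
  out[is.na(x)] <- NA_character_
  out
}

#' Default food composition table
#'
#' A compact synthetic composition table in the style of a national nutrient
#' database extract: for each food item, the water fraction of the edible
#' portion and a typical serving size in grams. It stands in for the full
#' food-frequency item list, which is configurable (the instrument's complete
#' item list is not fixed by this package).
#'
#' @return data.frame with columns `item`, `water_fraction`, `serving_size`.
#' @export
default_composition <- function() {
  data.frame(
    item = c("soup", "salad_greens", "rice", "pasta", "bread", "cheese",
             "meat", "fish", "legumes", "potato", "fruit", "vegetables_cooked",
             "yogurt", "eggs"),
    water_fraction = c(0.92, 0.93, 0.68, 0.62, 0.36, 0.37,
                       0.60, 0.70, 0.70, 0.77, 0.86, 0.93,
                       0.85, 0.75),
    serving_size = c(250, 150, 150, 180, 60, 30,
                     150, 150, 200, 200, 150, 150,
                     200, 100),
    stringsAsFactors = FALSE
  )
}

#' Default beverage serving table
#'
#' Serving volume (mL) and water fraction for the five beverage categories.
#' The instrument itself does not fix these; the defaults are typical Greek
#' serving sizes and are fully config-overridable.
#'
#' @return data.frame with columns `beverage`, `serving_ml`, `water_fraction`.
#' @export
default_beverage_servings <- function() {
  data.frame(
    beverage = WBQ_BEVERAGES,
    serving_ml = c(330, 150, 250, 250, 330),
    water_fraction = c(0.90, 0.95, 0.80, 0.99, 0.92),
    stringsAsFactors = FALSE
  )
}

#' Default scoring configuration
#'
#' Bundles every mapping table the scoring algorithm needs:
#' \itemize{
#'   \item `frequency_recode`: the six times/day constants.
#'   \item `composition`: food item -> (water fraction, serving g).
#'   \item `beverage_servings`: beverage category -> (serving mL, water fraction).
#'   \item `urine_loss_map`: 5-point urination scale -> mL/day, a linear grid
#'     800-2000 mL spanning reported daily urinary water loss in healthy adults.
#'   \item `fecal_loss_map`: 5-point defecation scale -> mL/day (50-400 mL,
#'     spanning published fecal water for healthy adults).
#'   \item `sweat_rest_map`: 10-point resting-sweat scale -> mL/day
#'     (linear 300-1000 mL).
#'   \item `sweat_exercise_rates`: base sweat rates in mL/hour for vigorous
#'     (1000), moderate (600) and walking (300) activity.
#'   \item `sweat_scale_multipliers`: 10-point exercise-sweat scale ->
#'     multiplier (linear 0.2-2.0).
#' }
#' The excretion-scale anchors are package defaults, not published constants;
#' every entry can be overridden via a YAML/JSON config so sensitivity analyses
#' are a single config swap.
#'
#' @param ... named elements overriding individual defaults.
#' @return An object of class `wbq_config` (a named list).
#' @export
#' @examples
#' cfg <- wbq_default_config()
#' cfg$urine_loss_map
wbq_default_config <- function(...) {
  cfg <- list(
    frequency_recode = default_frequency_recode(),
    composition = default_composition(),
    beverage_servings = default_beverage_servings(),
    urine_loss_map = c(800, 1100, 1400, 1700, 2000),
    fecal_loss_map = c(50, 100, 150, 250, 400),
    sweat_rest_map = seq(300, 1000, length.out = 10),
    sweat_exercise_rates = c(vigorous = 1000, moderate = 600, walking = 300),
    sweat_scale_multipliers = seq(0.2, 2.0, length.out = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "wbq_config"
  validate_scoring_config(cfg)
  cfg
}

#' Validate a scoring configuration
#'
#' Checks totality and non-negativity of every mapping table and the ordering
#' of the frequency recode. Called by every scoring entry point.
#'
#' @param config a `wbq_config` list.
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_scoring_config <- function(config) {
  stopifnot(is.list(config))
  fr <- config$frequency_recode
  if (length(fr) != 6L || !all(names(fr) == WBQ_FREQ_LEVELS))
    stop("frequency_recode must have exactly the 6 canonical categories, in order")
  if (any(fr < 0) || any(diff(fr) < 0))
    stop("frequency_recode values must be non-negative and non-decreasing")
  comp <- config$composition
  if (!all(c("item", "water_fraction", "serving_size") %in% names(comp)))
    stop("composition must have columns item, water_fraction, serving_size")
  if (any(comp$water_fraction < 0 | comp$water_fraction > 1))
    stop("composition water fractions must lie in [0, 1]")
  if (any(comp$serving_size < 0)) stop("composition serving sizes must be >= 0")
  if (anyDuplicated(comp$item)) stop("duplicated item in composition table")
  bev <- config$beverage_servings
  if (!setequal(bev$beverage, WBQ_BEVERAGES))
    stop("beverage_servings must cover exactly the 5 beverage categories")
  if (any(bev$serving_ml < 0) || any(bev$water_fraction < 0 | bev$water_fraction > 1))
    stop("beverage_servings values out of range")
  if (length(config$urine_loss_map) != 5L || any(config$urine_loss_map < 0))
    stop("urine_loss_map must map scales 1-5 to non-negative mL/day")
  if (length(config$fecal_loss_map) != 5L || any(config$fecal_loss_map < 0))
    stop("fecal_loss_map must map scales 1-5 to non-negative mL/day")
  if (length(config$sweat_rest_map) != 10L || any(config$sweat_rest_map < 0))
    stop("sweat_rest_map must map scales 1-10 to non-negative mL/day")
  if (!all(c("vigorous", "moderate", "walking") %in% names(config$sweat_exercise_rates)))
    stop("sweat_exercise_rates must name vigorous, moderate and walking")
  if (any(config$sweat_exercise_rates < 0)) stop("sweat_exercise_rates must be >= 0")
  if (length(config$sweat_scale_multipliers) != 10L ||
      any(config$sweat_scale_multipliers < 0))
    stop("sweat_scale_multipliers must map scales 1-10 to non-negative multipliers")
  invisible(config)
}

#' Read / write a scoring configuration as YAML or JSON
#'
#' The on-disk document mirrors the list layout of [wbq_default_config()];
#' tables are stored as column lists. The format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return For `read_scoring_config`, a validated `wbq_config`.
#' @export
read_scoring_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- wbq_default_config()
  for (nm in intersect(names(raw), names(cfg))) {
    val <- raw[[nm]]
    if (nm %in% c("composition", "beverage_servings")) val <- as.data.frame(val)
    if (nm %in% c("frequency_recode", "sweat_exercise_rates"))
      val <- stats::setNames(as.numeric(unlist(val)), names(val))
    if (nm %in% c("urine_loss_map", "fecal_loss_map", "sweat_rest_map",
                  "sweat_scale_multipliers"))
      val <- as.numeric(val)
    cfg[[nm]] <- val
  }
  class(cfg) <- "wbq_config"
  validate_scoring_config(cfg)
  cfg
}

#' @rdname read_scoring_config
#' @param config a `wbq_config`.
#' @export
write_scoring_config <- function(config, path) {
  validate_scoring_config(config)
  obj <- unclass(config)
  obj$composition <- as.list(obj$composition)
  obj$beverage_servings <- as.list(obj$beverage_servings)
  # named atomic vectors would lose their names in JSON arrays
  obj$frequency_recode <- as.list(obj$frequency_recode)
  obj$sweat_exercise_rates <- as.list(obj$sweat_exercise_rates)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
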