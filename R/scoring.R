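# Scoring: raw questionnaire answers -> per-respondent water intake, loss and
# balance components (mL/day) plus derived covariates (BMI, beverage variety,
# IPAQ activity). All operations are vectorized and deterministic; missing
# inputs propagate to missing outputs (imputation happens downstream).

#' Recode a consumption-frequency category to times/day
#'
#' @param category character vector of frequency labels (lexical variants of
#'   the six categories are accepted, see [canonical_frequency_label()]).
#' @param config named numeric recode vector (default the published constants,
#'   [default_frequency_recode()]).
#' @return numeric vector of daily frequencies; `NA` in gives `NA` out.
#' @export
#' @examples
#' recode_frequency("1-2 times per day")   # 0.643
#' recode_frequency("never/rarely")        # 0
recode_frequency <- function(category, config = default_frequency_recode()) {
  if (length(config) != 6L || is.null(names(config)))
    stop("frequency recode config must be a named vector over the 6 categories")
  canon <- canonical_frequency_label(category)
  unknown <- !is.na(category) & is.na(canon)
  if (any(unknown))
    stop("unknown frequency categor",
         if (sum(unknown) > 1) "ies: " else "y: ",
         paste(unique(category[unknown]), collapse = ", "))
  out <- unname(config[canon])
  out[is.na(canon)] <- NA_real_
  out
}

#' Water from foods (mL/day)
#'
#' For each food item, daily frequency (recoded) times serving size (g) times
#' water fraction; item contributions are summed. Water content of foods is
#' taken from the composition table of the scoring config. An item with a
#' missing frequency contributes 0 mL and is counted in the
#' `n_missing_items` attribute (scored respondents are flagged downstream).
#'
#' @param food_freq named list/vector (single respondent) or data.frame of
#'   `food_<item>` columns (cohort) of frequency labels.
#' @param config a `wbq_config`.
#' @return numeric vector of mL/day, attribute `n_missing_items`.
#' @export
water_from_foods <- function(food_freq, config = wbq_default_config()) {
  comp <- config$composition
  if (!is.data.frame(food_freq))
    food_freq <- as.data.frame(as.list(food_freq), stringsAsFactors = FALSE)
  items <- sub("^food_", "", names(food_freq))
  absent <- setdiff(items, comp$item)
  if (length(absent))
    stop("item(s) absent from composition table: ", paste(absent, collapse = ", "))
  total <- numeric(nrow(food_freq))
  n_miss <- integer(nrow(food_freq))
  for (j in seq_along(items)) {
    f <- recode_frequency(food_freq[[j]], config$frequency_recode)
    k <- match(items[j], comp$item)
    contrib <- f * comp$serving_size[k] * comp$water_fraction[k]
    n_miss <- n_miss + is.na(contrib)
    contrib[is.na(contrib)] <- 0
    total <- total + contrib
  }
  attr(total, "n_missing_items") <- n_miss
  total
}

#' Water from (non-water) beverages (mL/day)
#'
#' Sum over the five beverage categories of recoded daily frequency times
#' serving volume times water fraction. Plain drinking water is deliberately
#' not part of this component: it is recorded separately as
#' `drinking_water_ml`. A missing beverage frequency propagates to a missing
#' total (the five categories are a mandatory block of the instrument).
#'
#' @param beverage_freq named list/vector (single respondent) or data.frame of
#'   `bev_<category>` columns (cohort) of frequency labels.
#' @param config a `wbq_config`.
#' @return numeric vector of mL/day.
#' @export
water_from_beverages <- function(beverage_freq, config = wbq_default_config()) {
  bev <- config$beverage_servings
  if (!is.data.frame(beverage_freq))
    beverage_freq <- as.data.frame(as.list(beverage_freq), stringsAsFactors = FALSE)
  cats <- sub("^bev_", "", names(beverage_freq))
  if (!setequal(cats, WBQ_BEVERAGES))
    stop("beverage_freq must contain exactly the 5 beverage categories")
  total <- numeric(nrow(beverage_freq))
  for (j in seq_along(cats)) {
    f <- recode_frequency(beverage_freq[[j]], config$frequency_recode)
    k <- match(cats[j], bev$beverage)
    total <- total + f * bev$serving_ml[k] * bev$water_fraction[k]
  }
  total
}

#' Beverage variety score
#'
#' Counts the beverage categories with recoded daily frequency strictly above
#' zero (i.e. anything above never/rarely) and dichotomizes at the median
#' cutoff of 3: more than three distinct beverage types scores 1 (broader
#' variety), three or fewer scores 0 (limited variety).
#'
#' @inheritParams water_from_beverages
#' @return data.frame with columns `count` (0-5) and `binary` (0/1); `NA` if
#'   any category is missing.
#' @export
beverage_variety <- function(beverage_freq, config = wbq_default_config()) {
  if (!is.data.frame(beverage_freq))
    beverage_freq <- as.data.frame(as.list(beverage_freq), stringsAsFactors = FALSE)
  cats <- sub("^bev_", "", names(beverage_freq))
  if (!setequal(cats, WBQ_BEVERAGES))
    stop("beverage_freq must contain exactly the 5 beverage categories")
  consumed <- sapply(seq_along(cats), function(j)
    recode_frequency(beverage_freq[[j]], config$frequency_recode) > 0)
  consumed <- matrix(consumed, nrow = nrow(beverage_freq))
  count <- rowSums(consumed)            # NA if any category missing
  data.frame(count = count, binary = as.integer(count > 3))
}

check_scale <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
  if (any(bad))
    stop(what, " out of range ", lo, "-", hi, ": ",
         paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

#' Urinary and fecal water loss (mL/day)
#'
#' Table lookups of the 5-point excretion-frequency scales in the configured
#' loss maps (monotone non-decreasing by construction of the defaults).
#'
#' @param scale integer vector in 1-5 (NA allowed).
#' @param config a `wbq_config`.
#' @return numeric vector of mL/day.
#' @export
urine_loss <- function(scale, config = wbq_default_config()) {
  check_scale(scale, 1, 5, "urination scale")
  config$urine_loss_map[scale]
}

#' @rdname urine_loss
#' @export
fecal_loss <- function(scale, config = wbq_default_config()) {
  check_scale(scale, 1, 5, "defecation scale")
  config$fecal_loss_map[scale]
}

#' Sweat water loss (mL/day)
#'
#' Resting component: lookup of the 10-point resting-sweat scale in
#' `sweat_rest_map`. Exercise component: for each activity class (vigorous,
#' moderate, walking), weekly hours / 7 times the class base rate (mL/h)
#' times the exercise-sweat scale multiplier; classes are summed. Weekly hours
#' come from the activity recall (days/week x minutes/session).
#'
#' @param sweat_rest_scale,sweat_exercise_scale integer vectors in 1-10.
#' @param ipaq data.frame (or named list) with columns
#'   `ipaq_vigorous_days`, `ipaq_vigorous_min`, `ipaq_moderate_days`,
#'   `ipaq_moderate_min`, `ipaq_walking_days`, `ipaq_walking_min`.
#' @param config a `wbq_config`.
#' @return numeric vector of mL/day.
#' @export
sweat_loss <- function(sweat_rest_scale, sweat_exercise_scale, ipaq,
                       config = wbq_default_config()) {
  check_scale(sweat_rest_scale, 1, 10, "resting sweat scale")
  check_scale(sweat_exercise_scale, 1, 10, "exercise sweat scale")
  if (!is.data.frame(ipaq)) ipaq <- as.data.frame(as.list(ipaq))
  rest <- config$sweat_rest_map[sweat_rest_scale]
  mult <- config$sweat_scale_multipliers[sweat_exercise_scale]
  hours <- function(cls)
    ipaq[[paste0("ipaq_", cls, "_days")]] * ipaq[[paste0("ipaq_", cls, "_min")]] / 60
  exercise <- 0
  for (cls in c("vigorous", "moderate", "walking")) {
    h <- hours(cls)
    if (any(!is.na(h) & h < 0)) stop("negative activity duration")
    exercise <- exercise + (h / 7) * config$sweat_exercise_rates[[cls]] * mult
  }
  rest + exercise
}

#' Body mass index and its WHO category
#'
#' BMI = weight (kg) / height (m) squared. Categories per WHO: `<18.5`
#' underweight, `[18.5, 25)` normal, `[25, 30)` overweight, `>= 30` obese
#' (boundaries inclusive on the left).
#'
#' @param weight_kg,height_m positive numerics (NA allowed).
#' @return numeric BMI in kg/m2.
#' @export
#' @examples
#' compute_bmi(70, 1.70)          # 24.22
#' categorize_bmi(c(18.5, 30))    # "normal", "obese"
compute_bmi <- function(weight_kg, height_m) {
  bad <- (!is.na(weight_kg) & weight_kg <= 0) | (!is.na(height_m) & height_m <= 0)
  if (any(bad)) stop("weight and height must be positive")
  weight_kg / height_m^2
}

#' @rdname compute_bmi
#' @param bmi numeric BMI values.
#' @export
categorize_bmi <- function(bmi) {
  as.character(cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
                   labels = c("underweight", "normal", "overweight", "obese")))
}

#' Physical-activity score (short-recall MET minutes per week)
#'
#' Standard short-form scoring: 8.0 MET for vigorous activity, 4.0 for
#' moderate activity, 3.3 for walking, each multiplied by days/week x
#' minutes/session and summed.
#'
#' @inheritParams sweat_loss
#' @return numeric vector of MET-min/week.
#' @export
score_ipaq <- function(ipaq) {
  if (!is.data.frame(ipaq)) ipaq <- as.data.frame(as.list(ipaq))
  for (cls in c("vigorous", "moderate", "walking")) {
    d <- ipaq[[paste0("ipaq_", cls, "_days")]]
    m <- ipaq[[paste0("ipaq_", cls, "_min")]]
    if (any(!is.na(d) & (d < 0 | d > 7))) stop("activity days must lie in 0-7")
    if (any(!is.na(m) & m < 0)) stop("activity minutes must be >= 0")
  }
  8.0 * ipaq$ipaq_vigorous_days * ipaq$ipaq_vigorous_min +
    4.0 * ipaq$ipaq_moderate_days * ipaq$ipaq_moderate_min +
    3.3 * ipaq$ipaq_walking_days * ipaq$ipaq_walking_min
}

#' Assemble intake, loss and balance from computed components
#'
#' Water balance is total fluid intake (foods + beverages + drinking water)
#' minus total fluid loss (urine + feces + sweat). Respiratory water loss and
#' metabolic water production are both omitted: they are nearly equal in
#' magnitude and opposite in sign, so they cancel in the balance. Any missing
#' component propagates to a missing total/balance and sets `complete = FALSE`.
#'
#' @param water_from_foods,water_from_beverages,water_from_water,urine_loss,fecal_loss,sweat_loss
#'   numeric component vectors (mL/day).
#' @return data.frame with `intake_total`, `loss_total`, `balance`, `complete`.
#' @export
compute_balance <- function(water_from_foods, water_from_beverages,
                            water_from_water, urine_loss, fecal_loss,
                            sweat_loss) {
  intake <- water_from_foods + water_from_beverages + water_from_water
  loss <- urine_loss + fecal_loss + sweat_loss
  data.frame(intake_total = intake, loss_total = loss,
             balance = intake - loss,
             complete = !is.na(intake) & !is.na(loss))
}

#' Score a cohort of questionnaire responses
#'
#' Runs every scoring operation over a typed response table (one row per
#' respondent) and returns the water profile: intake components, loss
#' components, balance, beverage variety, BMI (+ WHO class) and the weekly
#' activity score. The returned table keeps the input columns (so downstream
#' analysis has both raw covariates and the profile) followed by the profile
#' columns.
#'
#' @param data typed response data.frame (as from [read_responses()] or
#'   [generate_cohort()]).
#' @param config a `wbq_config`.
#' @param keep_inputs keep the input columns in the output (default TRUE).
#' @return data.frame: input columns (optionally) plus
#'   `water_from_foods`, `water_from_beverages`, `water_from_water`,
#'   `intake_total`, `urine_loss`, `fecal_loss`, `sweat_loss`, `loss_total`,
#'   `balance`, `complete`, `beverage_variety_count`,
#'   `beverage_variety_binary`, `bmi`, `bmi_category`, `ipaq_met_min_week`.
#' @export
score_wbq <- function(data, config = wbq_default_config(), keep_inputs = TRUE) {
  validate_scoring_config(config)
  food_cols <- grep("^food_", names(data), value = TRUE)
  bev_cols <- paste0("bev_", WBQ_BEVERAGES)
  if (!all(bev_cols %in% names(data)))
    stop("response table lacks the 5 beverage frequency columns")
  foods <- if (length(food_cols))
    water_from_foods(data[food_cols], config) else numeric(nrow(data))
  bevs <- water_from_beverages(data[bev_cols], config)
  variety <- beverage_variety(data[bev_cols], config)
  ur <- urine_loss(data$urination_scale, config)
  fe <- fecal_loss(data$defecation_scale, config)
  sw <- sweat_loss(data$sweat_rest_scale, data$sweat_exercise_scale, data, config)
  bal <- compute_balance(as.numeric(foods), bevs, data$drinking_water_ml,
                         ur, fe, sw)
  bmi <- compute_bmi(data$weight_kg, data$height_m)
  profile <- data.frame(
    water_from_foods = as.numeric(foods),
    water_from_beverages = bevs,
    water_from_water = data$drinking_water_ml,
    intake_total = bal$intake_total,
    urine_loss = ur, fecal_loss = fe, sweat_loss = sw,
    loss_total = bal$loss_total,
    balance = bal$balance,
    complete = bal$complete,
    beverage_variety_count = variety$count,
    beverage_variety_binary = variety$binary,
    bmi = bmi,
    bmi_category = categorize_bmi(bmi),
    ipaq_met_min_week = score_ipaq(data),
    stringsAsFactors = FALSE)
  if (keep_inputs) cbind(data, profile) else
    cbind(data.frame(id = data$id, stringsAsFactors = FALSE), profile)
}
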