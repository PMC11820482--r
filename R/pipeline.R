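# Pipeline entry points: simulate -> score -> analyze, individually or as one
# run with a JSON manifest tying configs, seeds and output hashes together.

.stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

.hash_obj <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Simulate a synthetic cohort to CSV
#'
#' Generates a cohort from a spec (optionally read from YAML/JSON) and writes
#' it as a response CSV that is a valid input to [wbq_score()].
#'
#' @param out output CSV path.
#' @param spec a `wbq_cohort_spec`, or path to a YAML/JSON document with
#'   fields overriding [cohort_spec()] defaults (`n`, `seed`, `intercept`,
#'   `noise_sd`, `true_coefficients`).
#' @param seed overrides the spec seed if non-NULL.
#' @param config scoring config used for the back-solve.
#' @return `out`, invisibly; the written cohort as attribute `data`.
#' @export
wbq_simulate <- function(out, spec = cohort_spec(), seed = NULL,
                         config = wbq_default_config()) {
  if (is.character(spec)) {
    raw <- if (grepl("\\.json$", spec, ignore.case = TRUE))
      jsonlite::read_json(spec, simplifyVector = TRUE) else yaml::read_yaml(spec)
    args <- raw[intersect(names(raw), c("n", "seed", "intercept", "noise_sd"))]
    if (!is.null(raw$true_coefficients))
      args$true_coefficients <- unlist(raw$true_coefficients)
    spec <- do.call(cohort_spec, args)
  }
  if (!is.null(seed)) spec$seed <- seed
  cohort <- generate_cohort(spec, config)
  write_responses(cohort, out)
  invisible(structure(out, data = cohort))
}

#' Score a response CSV
#'
#' Reads and validates responses, applies the exclusion criteria, scores the
#' retained respondents and writes the scored table (input columns + water
#' profile) to CSV.
#'
#' @param responses input CSV path.
#' @param out output CSV path.
#' @param config a `wbq_config` or path to a YAML/JSON scoring config.
#' @param codebook a `wbq_codebook` (default derived from the config's
#'   composition items).
#' @return `out`, invisibly; scored table as attribute `data`, exclusion log
#'   as attribute `exclusions`, validation errors as attribute `errors`.
#' @export
wbq_score <- function(responses, out, config = wbq_default_config(),
                      codebook = NULL) {
  if (is.character(config)) config <- read_scoring_config(config)
  if (is.null(codebook)) codebook <- wbq_codebook(config$composition$item)
  data <- read_responses(responses, codebook)
  errs <- attr(data, "validation_errors")
  filt <- exclusion_filter(data)
  scored <- score_wbq(filt$retained, config)
  write_responses(scored, out)
  invisible(structure(out, data = scored, exclusions = filt$log, errors = errs))
}

.read_scored <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("balance", "gender", MODEL1_TERMS)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("scored table lacks column(s): ", paste(miss, collapse = ", "),
         " (is this the output of wbq_score?)")
  d
}

#' Analyze a scored cohort
#'
#' Reproduces the study's full statistical pipeline on a scored table and
#' writes: `table1.csv` (demographics by gender), `table2.csv` (working
#' environment), `table3.csv` (water intake and discharge), `table4.csv`
#' (univariate water-balance screen), `table5.csv` (the three multivariable
#' models, imputation-pooled), and `diagnostics.json` (missingness screen,
#' VIF, residual checks, imputation metadata).
#'
#' @param scored path to the scored CSV from [wbq_score()].
#' @param out_dir output directory (created if needed).
#' @param m,maxit,seed imputation parameters.
#' @return character vector of written file paths, invisibly; model fits as
#'   attribute `models`.
#' @export
wbq_analyze <- function(scored, out_dir, m = 20, maxit = 10, seed = 20220512) {
  d <- .read_scored(scored)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(tab, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(tab, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  d$bev_rate_juices_soda <- recode_frequency(d$bev_juices_soda)
  d$bev_rate_coffee_milk <- recode_frequency(d$bev_coffee_milk)
  d$bev_rate_milkshake_granita <- recode_frequency(d$bev_milkshake_granita)
  d$bev_rate_tea <- recode_frequency(d$bev_tea)
  d$bev_rate_alcohol <- recode_frequency(d$bev_alcohol)

  wr(descriptive_table(d, c("residence", "family_status", "profession",
                            "bmi", "bmi_category")), "table1.csv")
  wr(descriptive_table(d, c("work_hours_week", "labor_intensity",
                            "physical_strain", "mental_strain", "wc_access",
                            "weather_exposure", "water_access",
                            "bottle_at_work", "bottle_during_day",
                            "glass_during_day")), "table2.csv")
  wr(descriptive_table(d, c("water_from_foods", "water_from_beverages",
                            "bev_rate_juices_soda", "bev_rate_coffee_milk",
                            "bev_rate_milkshake_granita", "bev_rate_tea",
                            "bev_rate_alcohol", "beverage_variety_binary",
                            "water_from_water", "intake_total", "loss_total",
                            "balance")), "table3.csv")

  ad <- analysis_data(d)
  screen <- univariate_screen(ad)
  wr(screen, "table4.csv")

  mar <- assess_mar(ad)
  imp <- impute_chained(ad, m = m, maxit = maxit, seed = seed)
  models <- fit_model_sequence(imp)
  stack <- function(fit, label) {
    if (is.null(fit)) return(NULL)
    cbind(model = label, fit$table,
          adj_r2 = c(fit$adj_r2, rep(NA, nrow(fit$table) - 1)),
          rmse = c(fit$rmse, rep(NA, nrow(fit$table) - 1)))
  }
  wr(rbind(stack(models$model1, "model1"), stack(models$model2, "model2"),
           stack(models$model3, "model3")), "table5.csv")

  diag1 <- model_diagnostics(models$model1)
  p <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(list(
    n = nrow(d),
    missingness = list(
      variables = imp$vars,
      methods = as.list(imp$methods),
      systematic_pattern = as.list(attr(mar, "systematic_pattern")),
      m = imp$m, maxit = imp$maxit, seed = imp$seed),
    model1_diagnostics = list(
      vif = as.list(diag1$vif), vif_flagged = diag1$vif_flagged,
      shapiro_w = diag1$shapiro_w, shapiro_p = diag1$shapiro_p,
      bp_p = diag1$bp_p),
    selected_terms = models$selected_terms),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(structure(paths, models = models, mar = mar))
}

#' Run the full pipeline with a manifest
#'
#' `simulate -> score -> analyze`, each stage consuming the previous stage's
#' CSV, with a JSON run manifest recording tool version, config hashes, seed,
#' every output path with its MD5, timestamps and per-stage status. A failed
#' stage halts the run (the manifest records the failure; earlier outputs are
#' retained). Identical spec + config + seed give byte-identical CSV outputs.
#'
#' @param out_dir output directory.
#' @param spec cohort spec (object or YAML/JSON path).
#' @param config scoring config (object or path).
#' @param seed seed overriding the spec's (also used for analysis imputation).
#' @param m,maxit imputation parameters for the analyze stage.
#' @return manifest list, invisibly; written to `manifest.json` in `out_dir`.
#' @export
wbq_run <- function(out_dir, spec = cohort_spec(), config = wbq_default_config(),
                    seed = NULL, m = 20, maxit = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_scoring_config(config)
  manifest <- list(
    tool = paste0("wbq ", as.character(utils::packageVersion("wbq"))),
    started = .stamp(),
    seed = seed,
    config_hash = .hash_obj(list(spec = if (is.character(spec)) spec else
                                   unclass(spec)[c("n", "seed", "intercept",
                                                   "noise_sd", "true_coefficients")],
                                 config = lapply(unclass(config), function(x)
                                   if (is.data.frame(x)) as.list(x) else x))),
    stages = list(), files = list())
  cohort_csv <- file.path(out_dir, "cohort.csv")
  scored_csv <- file.path(out_dir, "scored.csv")
  run_stage <- function(name, fun) {
    st <- list(name = name, started = .stamp())
    res <- tryCatch(fun(), error = function(e) e)
    st$finished <- .stamp()
    st$status <- if (inherits(res, "error")) "failed" else "ok"
    if (inherits(res, "error")) st$error <- conditionMessage(res)
    manifest$stages[[name]] <<- st
    if (inherits(res, "error")) {
      manifest$finished <<- .stamp()
      .write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }
  run_stage("simulate", function()
    wbq_simulate(cohort_csv, spec, seed = seed, config = config))
  run_stage("score", function() wbq_score(cohort_csv, scored_csv, config))
  analysis_seed <- if (is.null(seed)) 20220512 else seed
  files <- run_stage("analyze", function()
    wbq_analyze(scored_csv, out_dir, m = m, maxit = maxit, seed = analysis_seed))
  manifest$finished <- .stamp()
  all_files <- c(cohort_csv, scored_csv, as.character(files))
  manifest$files <- lapply(all_files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
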