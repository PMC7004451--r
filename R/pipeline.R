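#' Pipeline configuration
#'
#' Defaults describe the synthetic study the package ships with: a handful
#' of weather stations and PM2.5 monitors scattered over a southern-US
#' bounding box, pregnancies with delivery dates spread over several years
#' (so conception dates cover all seasons), and a true outcome model with a
#' positive PM-by-heat interaction on the odds scale.
#'
#' @param output_dir directory for all stage outputs.
#' @param seed integer seed recorded in output provenance and used for
#'   every random draw.
#' @param n_stations,n_monitors,n_subjects simulation sizes.
#' @param start_date,end_date daily-series date range (must cover every
#'   critical window implied by `edd_range`).
#' @param edd_range EDD range of the simulated pregnancies.
#' @param residence_box named vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param model a [true_model()] for outcome generation.
#' @param n_cases,n_controls case-control sample drawn from the cohort.
#' @param ehe_definitions character vector among `"EHE95"`, `"EHE90"`.
#' @param pm_percentile control percentile for the PM2.5 cut (default 80).
#' @param min_days minimum in-window monitor days (default 28).
#' @param max_monitor_km monitor linkage cap, km (default 50).
#' @param population_filters filters passed to [run_analysis()].
#' @param outcome_groups case groups passed to [run_analysis()].
#' @param weather_csv,monitors_csv,subjects_csv,exposure_csv file paths;
#'   defaults live under `output_dir`.
#' @param ... reserved; unknown keys are an error (config typos should not
#'   pass silently).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("heatpm_"), seed = 1L,
                            n_stations = 4L, n_monitors = 6L,
                            n_subjects = 25000L,
                            start_date = "1998-01-01",
                            end_date = "2002-12-31",
                            edd_range = c("1999-01-01", "2002-06-30"),
                            residence_box = c(lat_min = 31, lat_max = 33,
                                              lon_min = -92, lon_max = -90),
                            model = true_model(
                              intercept = stats::qlogis(0.08),
                              beta_pm = 0, beta_ehe = log(1.2),
                              beta_interaction = log(1.6),
                              covariate_betas = list(
                                maternal_age_cat = c("<=19" = 0.10,
                                                     ">=35" = 0.15),
                                education_cat = c("<12y" = 0.10),
                                race_ethnicity = c("NH-black" = 0.10,
                                                   "Hispanic" = 0.05)),
                              beta_dew_point = 0.01),
                            n_cases = 1000L, n_controls = 1500L,
                            ehe_definitions = c("EHE95", "EHE90"),
                            pm_percentile = 80, min_days = 28L,
                            max_monitor_km = 50,
                            population_filters = c("full",
                                                   "any_spring_summer",
                                                   "entire_spring_summer",
                                                   "any_summer"),
                            outcome_groups = "VSDpm",
                            weather_csv = NULL, monitors_csv = NULL,
                            subjects_csv = NULL, exposure_csv = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    output_dir = output_dir, seed = as.integer(seed),
    n_stations = n_stations, n_monitors = n_monitors,
    n_subjects = n_subjects, start_date = start_date, end_date = end_date,
    edd_range = edd_range, residence_box = residence_box, model = model,
    n_cases = n_cases, n_controls = n_controls,
    ehe_definitions = ehe_definitions, pm_percentile = pm_percentile,
    min_days = min_days, max_monitor_km = max_monitor_km,
    population_filters = population_filters,
    outcome_groups = outcome_groups,
    weather_csv = weather_csv %||% file.path(output_dir, "weather.csv"),
    monitors_csv = monitors_csv %||% file.path(output_dir, "monitors.csv"),
    subjects_csv = subjects_csv %||% file.path(output_dir, "subjects.csv"),
    exposure_csv = exposure_csv %||% file.path(output_dir, "exposure.csv")
  )
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; the `model` key, if
#' present, is a mapping of [true_model()] arguments. Unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$model)) raw$model <- do.call(true_model, raw$model)
  if (!is.null(raw$residence_box)) {
    raw$residence_box <- unlist(raw$residence_box)
  }
  do.call(pipeline_config, raw)
}

# Provenance-headed CSV: '#'-prefixed key/value lines, then the table.
.write_csv_prov <- function(df, path, config, stage) {
  df <- as.data.frame(df)
  for (nm in names(df)) if (inherits(df[[nm]], "Date")) {
    df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# heatpm %s", stage),
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("heatpm"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# rows: %d", nrow(df))
  ), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
}

.read_csv_prov <- function(path, date_cols = character()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (nm in intersect(date_cols, names(df))) df[[nm]] <- as.Date(df[[nm]])
  tibble::as_tibble(df)
}

#' Stage 1: simulate the study inputs
#'
#' Writes the three input CSVs (daily weather, daily PM2.5, subject table
#' with assigned case status) plus a YAML manifest of the true model
#' parameters, so downstream recovery checks know the generating truth.
#' Outcomes are generated from exposures dichotomized at the cohort
#' percentile (case status does not exist yet at generation time); the
#' analysis stage re-dichotomizes on controls per the study definition.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the three tibbles, the cohort, and the
#'   written paths.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_subjects <= 0) stop("n_subjects must be > 0", call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  box <- config$residence_box

  stations <- tibble::tibble(
    station_id = sprintf("W%03d", seq_len(config$n_stations)),
    latitude = stats::runif(config$n_stations, box[["lat_min"]],
                            box[["lat_max"]]),
    longitude = stats::runif(config$n_stations, box[["lon_min"]],
                             box[["lon_max"]]))
  monitors <- tibble::tibble(
    monitor_id = sprintf("M%03d", seq_len(config$n_monitors)),
    latitude = stats::runif(config$n_monitors, box[["lat_min"]],
                            box[["lat_max"]]),
    longitude = stats::runif(config$n_monitors, box[["lon_min"]],
                             box[["lon_max"]]))

  weather <- generate_weather(stations, config$start_date, config$end_date)
  pm <- generate_monitors(monitors, config$start_date, config$end_date)
  subjects <- generate_subjects(config$n_subjects,
                                residence_box = box,
                                edd_range = as.Date(config$edd_range))
  exposure <- build_exposure_table(
    subjects, weather, pm, min_days = config$min_days,
    pm_percentile = config$pm_percentile,
    max_monitor_km = config$max_monitor_km, dichotomize = "all")
  ok <- !is.na(exposure$pm_high)
  cohort <- assign_outcomes(subjects[ok, , drop = FALSE],
                            exposure[ok, , drop = FALSE], config$model)
  # subjects the PM linkage excluded keep NA case status out of the cohort
  subjects_out <- dplyr::bind_rows(cohort, subjects[!ok, , drop = FALSE])
  subjects_out <- subjects_out[order(subjects_out$subject_id), , drop = FALSE]
  study <- sample_case_control(cohort, config$n_cases, config$n_controls)
  study_out <- dplyr::bind_rows(
    study, subjects_out[is.na(subjects_out$is_case), , drop = FALSE])

  .write_csv_prov(weather, config$weather_csv, config, "weather series")
  .write_csv_prov(pm, config$monitors_csv, config, "PM2.5 monitor series")
  .write_csv_prov(study_out, config$subjects_csv, config,
                  "case-control subject table")
  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    generation_pm_threshold = attr(exposure, "pm_threshold"),
    true_model = list(
      intercept = config$model$intercept, beta_pm = config$model$beta_pm,
      beta_ehe = config$model$beta_ehe,
      beta_interaction = config$model$beta_interaction,
      beta_dew_point = config$model$beta_dew_point,
      ehe_definition = config$model$ehe_definition,
      true_or10 = config$model$true_or10,
      true_or01 = config$model$true_or01,
      true_or11 = config$model$true_or11,
      true_reri = config$model$true_reri))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(list(weather = weather, monitors = pm, subjects = study_out,
                 cohort = cohort,
                 paths = c(config$weather_csv, config$monitors_csv,
                           config$subjects_csv,
                           file.path(config$output_dir, "manifest.yaml"))))
}

#' Stage 2: assign exposures
#'
#' Reads the three input CSVs, runs the exposure-assignment chain
#' ([build_exposure_table()], control-percentile dichotomization) and
#' writes the exposure CSV: one row per subject, with subjects excluded by
#' the 50-km monitor rule present but PM-missing, carrying an
#' `exclusion_reason`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the exposure tibble (threshold in attribute
#'   `pm_threshold`).
#' @export
pipeline_expose <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  weather <- .read_csv_prov(config$weather_csv, "date")
  monitors <- .read_csv_prov(config$monitors_csv, "date")
  subjects <- .read_csv_prov(config$subjects_csv, "edd")
  subjects$is_case <- as.logical(subjects$is_case)
  defs <- lapply(config$ehe_definitions, ehe_definition)
  has_status <- any(subjects$is_case %in% FALSE)
  exposure <- build_exposure_table(
    subjects, weather, monitors, min_days = config$min_days,
    pm_percentile = config$pm_percentile,
    max_monitor_km = config$max_monitor_km, ehe_definitions = defs,
    dichotomize = if (has_status) "controls" else "none")
  .write_csv_prov(exposure, config$exposure_csv, config, "exposure table")
  invisible(exposure)
}

#' Stage 3: fit the interaction models
#'
#' Reads the subject and exposure CSVs, merges them, runs
#' [run_analysis()] over the configured grid, and writes the tidy results
#' CSV plus a human-readable report with a provenance block.
#'
#' @param config a [pipeline_config()].
#' @param profile_ci compute profile-likelihood RERI intervals.
#' @return invisibly, the results tibble.
#' @export
pipeline_analyze <- function(config, profile_ci = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- .read_csv_prov(config$subjects_csv, "edd")
  subjects$is_case <- as.logical(subjects$is_case)
  exposure <- .read_csv_prov(config$exposure_csv,
                             c("conception", "window_start", "window_end"))
  data <- dplyr::inner_join(subjects, exposure, by = "subject_id")
  data <- data[!is.na(data$is_case), , drop = FALSE]
  if (nrow(data) == 0) stop("empty analytic population", call. = FALSE)
  results <- run_analysis(data, config$outcome_groups,
                          config$ehe_definitions,
                          config$population_filters,
                          profile_ci = profile_ci)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv_prov(results, file.path(config$output_dir, "results.csv"),
                  config, "interaction results")
  report <- c(
    "heatpm interaction analysis",
    sprintf("seed: %d", config$seed),
    sprintf("subjects analyzed: %d (%d cases, %d controls)",
            nrow(data), sum(data$is_case), sum(!data$is_case)),
    sprintf("grid: %s x %s x %s",
            paste(config$outcome_groups, collapse = ","),
            paste(config$population_filters, collapse = ","),
            paste(config$ehe_definitions, collapse = ",")),
    "",
    utils::capture.output(print(as.data.frame(results), digits = 3)))
  writeLines(report, file.path(config$output_dir, "report.txt"))
  invisible(results)
}
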