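#' Default covariate distributions for the synthetic cohort
#'
#' Marginal distributions of the adjustment-set covariates, chosen to
#' resemble the demographic profile of a large US population-based birth
#' cohort: mostly ages 20-34, mostly at least 12 years of education, a
#' non-Hispanic-white majority with sizeable Hispanic and NH-black groups.
#'
#' @return named list of named probability vectors, one per categorical
#'   covariate (`maternal_age_cat`, `education_cat`, `race_ethnicity`,
#'   `climate_region`).
#' @export
default_covariate_probs <- function() {
  list(
    maternal_age_cat = c("<=19" = 0.10, "20-34" = 0.75, ">=35" = 0.15),
    education_cat = c("<12y" = 0.20, ">=12y" = 0.80),
    race_ethnicity = c("NH-white" = 0.60, "NH-black" = 0.12,
                       "Hispanic" = 0.22, "other" = 0.06),
    climate_region = c("South" = 0.50, "Southeast" = 0.50)
  )
}

.check_probs <- function(covariate_probs) {
  for (nm in names(covariate_probs)) {
    p <- covariate_probs[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("covariate_probs$", nm,
           " must be a named non-negative vector summing to 1", call. = FALSE)
    }
  }
  invisible(covariate_probs)
}

.sample_cat <- function(n, p) {
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic cohort of pregnancies
#'
#' Draws subjects with residence coordinates uniform over a bounding box,
#' estimated delivery dates (EDDs) uniform over a date range (so conception
#' dates span all seasons), gestational age from a rounded normal clipped to
#' 20-44 weeks, and categorical covariates drawn independently from the
#' supplied marginals. Case status is left unset; see [assign_outcomes()].
#'
#' @param n number of subjects (> 0).
#' @param residence_box named numeric vector `c(lat_min, lat_max, lon_min,
#'   lon_max)` in decimal degrees.
#' @param edd_range length-2 vector of `Date`s (inclusive) for the EDD.
#' @param covariate_probs see [default_covariate_probs()].
#' @param gestational_age_mean,gestational_age_sd parameters of the rounded
#'   normal for gestational age at delivery, weeks.
#' @param seed optional integer seed.
#' @return tibble with one row per subject: `subject_id`, `is_case` (NA),
#'   `outcome_group` (NA), `latitude`, `longitude`, `edd`,
#'   `gestational_age_weeks`, the categorical covariates, `climate_region`.
#' @export
generate_subjects <- function(n,
                              residence_box = c(lat_min = 30, lat_max = 36,
                                                lon_min = -100, lon_max = -80),
                              edd_range = as.Date(c("1999-01-01", "2007-12-31")),
                              covariate_probs = default_covariate_probs(),
                              gestational_age_mean = 38.7,
                              gestational_age_sd = 2.3,
                              seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  edd_range <- as.Date(edd_range)
  if (length(edd_range) != 2 || any(is.na(edd_range)) ||
      edd_range[1] > edd_range[2]) {
    stop("edd_range must be a valid non-empty date interval", call. = FALSE)
  }
  .check_probs(covariate_probs)
  if (!is.null(seed)) set.seed(seed)

  ndays <- as.integer(edd_range[2] - edd_range[1]) + 1L
  ga <- pmin(pmax(round(stats::rnorm(n, gestational_age_mean,
                                     gestational_age_sd)), 20L), 44L)
  tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    is_case = NA,
    outcome_group = NA_character_,
    latitude = stats::runif(n, residence_box[["lat_min"]],
                            residence_box[["lat_max"]]),
    longitude = stats::runif(n, residence_box[["lon_min"]],
                             residence_box[["lon_max"]]),
    edd = edd_range[1] + (sample.int(ndays, n, replace = TRUE) - 1L),
    gestational_age_weeks = as.integer(ga),
    maternal_age_cat = .sample_cat(n, covariate_probs$maternal_age_cat),
    education_cat = .sample_cat(n, covariate_probs$education_cat),
    race_ethnicity = .sample_cat(n, covariate_probs$race_ethnicity),
    climate_region = .sample_cat(n, covariate_probs$climate_region)
  )
}

#' Specify the true outcome model of the synthetic study
#'
#' Log-odds parameters of the generating logistic model for case status.
#' `beta_pm`, `beta_ehe` and `beta_interaction` are log odds ratios for high
#' PM2.5, EHE exposure and their product term; on the joint 4-level coding
#' the implied odds ratios are `OR10 = exp(beta_pm)`, `OR01 = exp(beta_ehe)`,
#' `OR11 = exp(beta_pm + beta_ehe + beta_interaction)`, and the implied
#' additive-scale interaction is `RERI = OR11 - OR10 - OR01 + 1`.
#'
#' @param intercept baseline log-odds of being a case (reference category,
#'   covariates at reference, dew point 0).
#' @param beta_pm,beta_ehe,beta_interaction log odds-ratio terms.
#' @param covariate_betas named list of named vectors: per covariate, the
#'   log-OR of each non-reference category (unlisted categories get 0).
#' @param beta_dew_point log-OR per degree C of window-mean dew point.
#' @param ehe_definition which heat-event metric drives the true model,
#'   `"EHE95"` or `"EHE90"`.
#' @return object of class `true_model`, including the implied `true_reri`
#'   and stratum odds ratios, with a human-readable `scale_note`.
#' @export
true_model <- function(intercept, beta_pm = 0, beta_ehe = 0,
                       beta_interaction = 0, covariate_betas = list(),
                       beta_dew_point = 0,
                       ehe_definition = c("EHE95", "EHE90")) {
  ehe_definition <- match.arg(ehe_definition)
  or10 <- exp(beta_pm)
  or01 <- exp(beta_ehe)
  or11 <- exp(beta_pm + beta_ehe + beta_interaction)
  reri <- or11 - or10 - or01 + 1
  structure(list(
    intercept = intercept, beta_pm = beta_pm, beta_ehe = beta_ehe,
    beta_interaction = beta_interaction, covariate_betas = covariate_betas,
    beta_dew_point = beta_dew_point, ehe_definition = ehe_definition,
    true_or10 = or10, true_or01 = or01, true_or11 = or11, true_reri = reri,
    scale_note = sprintf(
      "implied joint ORs: OR10=%.4g OR01=%.4g OR11=%.4g; true RERI=%.4g; OR(PM|EHE)=%.4g OR(PM|no EHE)=%.4g",
      or10, or01, or11, reri, exp(beta_pm + beta_interaction), or10)
  ), class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat("True logistic outcome model (", x$ehe_definition, " metric)\n", sep = "")
  cat(sprintf("  intercept %.4f  beta_pm %.4f  beta_ehe %.4f  beta_int %.4f\n",
              x$intercept, x$beta_pm, x$beta_ehe, x$beta_interaction))
  cat(" ", x$scale_note, "\n")
  invisible(x)
}

# Linear predictor of the true model on a merged subject/exposure frame.
.linpred <- function(model, df, pm, ehe) {
  lp <- model$intercept + model$beta_pm * pm + model$beta_ehe * ehe +
    model$beta_interaction * pm * ehe
  if (model$beta_dew_point != 0) {
    lp <- lp + model$beta_dew_point * df$mean_dew_point
  }
  for (nm in names(model$covariate_betas)) {
    b <- model$covariate_betas[[nm]]
    v <- b[match(df[[nm]], names(b))]
    v[is.na(v)] <- 0
    lp <- lp + unname(v)
  }
  lp
}

#' Assign case status from the true model
#'
#' Draws `is_case ~ Bernoulli(plogis(linear predictor))` for every subject
#' using its exposure record and the true model. Cases get
#' `outcome_group = case_group`; non-cases become controls.
#'
#' @param subjects subject tibble ([generate_subjects()]).
#' @param exposures exposure table with one row per subject (must contain
#'   `subject_id`, `pm_high`, the EHE flag named by the model, and
#'   `mean_dew_point` when the model uses dew point).
#' @param model a [true_model()].
#' @param seed optional integer seed.
#' @param case_group outcome-group label given to cases.
#' @return `subjects` with `is_case` and `outcome_group` filled in.
#' @export
assign_outcomes <- function(subjects, exposures, model, seed = NULL,
                            case_group = "VSDpm") {
  stopifnot(inherits(model, "true_model"))
  missing_ids <- setdiff(subjects$subject_id, exposures$subject_id)
  if (length(missing_ids) > 0) {
    stop("missing exposure record for ", length(missing_ids),
         " subject(s), e.g. ", missing_ids[1], call. = FALSE)
  }
  ehe_col <- paste0(tolower(model$ehe_definition), "_exposed")
  df <- dplyr::left_join(subjects, exposures, by = "subject_id")
  pm <- as.numeric(df$pm_high)
  ehe <- as.numeric(df[[ehe_col]])
  if (anyNA(pm) || anyNA(ehe)) {
    stop("assign_outcomes requires non-missing pm_high and ", ehe_col,
         " for every subject", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pr <- stats::plogis(.linpred(model, df, pm, ehe))
  subjects$is_case <- stats::runif(nrow(subjects)) < pr
  subjects$outcome_group <- ifelse(subjects$is_case, case_group, "control")
  subjects
}

#' Sample a case-control study from a cohort
#'
#' Outcome-dependent sampling without replacement: `n_cases` cases and
#' `n_controls` non-cases drawn at random. Sampling on outcome alone biases
#' only the logistic intercept, so exposure odds ratios are preserved in
#' expectation.
#'
#' @param cohort subject tibble with `is_case` set.
#' @param n_cases,n_controls requested counts.
#' @param seed optional integer seed.
#' @return tibble with exactly `n_cases + n_controls` rows.
#' @export
sample_case_control <- function(cohort, n_cases, n_controls, seed = NULL) {
  if (anyNA(cohort$is_case)) {
    stop("cohort has subjects without assigned case status", call. = FALSE)
  }
  case_idx <- which(cohort$is_case)
  ctrl_idx <- which(!cohort$is_case)
  if (length(case_idx) < n_cases) {
    stop("insufficient cases: ", length(case_idx), " available, ",
         n_cases, " requested", call. = FALSE)
  }
  if (length(ctrl_idx) < n_controls) {
    stop("insufficient controls: ", length(ctrl_idx), " available, ",
         n_controls, " requested", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- c(sample(case_idx, n_cases), sample(ctrl_idx, n_controls))
  cohort[sort(keep), , drop = FALSE]
}

#' Simulate a cohort directly from exposure indicators
#'
#' Tabular generator underlying [simulate_cc_study()]: draws dichotomous
#' high-PM2.5 and EHE indicators, adjustment-set covariates and window-mean
#' dew point for `n` pregnancies, and assigns case status from the true
#' logistic model. Both `ehe95_exposed` and `ehe90_exposed` carry the single
#' simulated heat indicator, and `any_day_spring_summer` is an independent
#' Bernoulli draw used only as a covariate under the full-population filter.
#'
#' @param n cohort size.
#' @param model a [true_model()].
#' @param p_pm_high,p_ehe,p_spring_summer marginal exposure/flag
#'   probabilities.
#' @param covariate_probs see [default_covariate_probs()].
#' @param dew_mean,dew_sd window-mean dew point distribution, degrees C.
#' @param seed optional integer seed.
#' @param case_group outcome-group label for cases.
#' @return tibble with one row per pregnancy: exposure indicators,
#'   covariates, `mean_dew_point`, `is_case`, `outcome_group`.
#' @export
simulate_cohort <- function(n, model, p_pm_high = 0.2, p_ehe = 0.35,
                            p_spring_summer = 0.6,
                            covariate_probs = default_covariate_probs(),
                            dew_mean = 12, dew_sd = 5, seed = NULL,
                            case_group = "VSDpm") {
  stopifnot(inherits(model, "true_model"), n > 0)
  .check_probs(covariate_probs)
  if (!is.null(seed)) set.seed(seed)
  pm <- stats::rbinom(n, 1, p_pm_high)
  ehe <- stats::rbinom(n, 1, p_ehe)
  df <- tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    pm_high = pm == 1,
    ehe95_exposed = ehe == 1,
    ehe90_exposed = ehe == 1,
    any_day_spring_summer = stats::rbinom(n, 1, p_spring_summer) == 1,
    maternal_age_cat = .sample_cat(n, covariate_probs$maternal_age_cat),
    education_cat = .sample_cat(n, covariate_probs$education_cat),
    race_ethnicity = .sample_cat(n, covariate_probs$race_ethnicity),
    mean_dew_point = stats::rnorm(n, dew_mean, dew_sd)
  )
  pr <- stats::plogis(.linpred(model, df, pm, ehe))
  df$is_case <- stats::runif(n) < pr
  df$outcome_group <- ifelse(df$is_case, case_group, "control")
  df
}

#' Simulate a case-control dataset directly from exposure indicators
#'
#' Tabular generator for calibration and coverage studies: draws dichotomous
#' high-PM2.5 and EHE exposure indicators, adjustment-set covariates and
#' window-mean dew point for a cohort, assigns case status from the true
#' logistic model, and samples the requested case-control study. The cohort
#' is grown in chunks until the requested counts are available, so the
#' returned study is an exact outcome-dependent sample.
#'
#' Both `ehe95_exposed` and `ehe90_exposed` columns are set to the single
#' simulated heat indicator: a calibration dataset carries one heat metric.
#' The `any_day_spring_summer` flag is an independent Bernoulli draw (used
#' only as a model covariate under the full-population filter).
#'
#' @param n_cases,n_controls study size.
#' @param model a [true_model()].
#' @param p_pm_high marginal probability of high PM2.5 (default 0.2, the
#'   80th-percentile cut).
#' @param p_ehe marginal probability of EHE exposure during the window
#'   (default 0.35, the order observed in warm-season US pregnancies).
#' @param p_spring_summer marginal probability of >= 1 window day in spring
#'   or summer (default 0.6).
#' @param covariate_probs see [default_covariate_probs()].
#' @param dew_mean,dew_sd window-mean dew point distribution, degrees C.
#' @param seed optional integer seed.
#' @param chunk_size cohort rows generated per chunk (default scales with the
#'   requested study size).
#' @param max_chunks safety cap on chunk draws before erroring.
#' @return tibble with one row per sampled subject: exposure indicators,
#'   covariates, `mean_dew_point`, `is_case`, `outcome_group`.
#' @export
simulate_cc_study <- function(n_cases, n_controls, model,
                              p_pm_high = 0.2, p_ehe = 0.35,
                              p_spring_summer = 0.6,
                              covariate_probs = default_covariate_probs(),
                              dew_mean = 12, dew_sd = 5,
                              seed = NULL, chunk_size = NULL,
                              max_chunks = 60L) {
  stopifnot(inherits(model, "true_model"), n_cases > 0, n_controls > 0)
  .check_probs(covariate_probs)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chunk_size)) {
    chunk_size <- max(20000L, 5L * (n_cases + n_controls))
  }

  gen_chunk <- function(m) {
    simulate_cohort(m, model, p_pm_high, p_ehe, p_spring_summer,
                    covariate_probs, dew_mean, dew_sd)
  }

  cases <- NULL
  ctrls <- NULL
  got_cases <- 0L
  got_ctrls <- 0L
  for (k in seq_len(max_chunks)) {
    ch <- gen_chunk(chunk_size)
    if (got_cases < n_cases) {
      cases <- dplyr::bind_rows(cases, ch[ch$is_case, , drop = FALSE])
      got_cases <- nrow(cases)
    }
    if (got_ctrls < n_controls) {
      ctrls <- dplyr::bind_rows(ctrls, ch[!ch$is_case, , drop = FALSE])
      got_ctrls <- nrow(ctrls)
    }
    if (got_cases >= n_cases && got_ctrls >= n_controls) break
  }
  if (got_cases < n_cases || got_ctrls < n_controls) {
    stop("could not accumulate the requested case/control counts; ",
         "check the model's implied prevalence", call. = FALSE)
  }
  out <- dplyr::bind_rows(cases[seq_len(n_cases), , drop = FALSE],
                          ctrls[seq_len(n_controls), , drop = FALSE])
  out$subject_id <- sprintf("S%06d", seq_len(nrow(out)))
  out$outcome_group <- ifelse(out$is_case, "VSDpm", "control")
  out
}
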