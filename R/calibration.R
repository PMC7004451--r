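#' Type-I error calibration of the interaction likelihood-ratio test
#'
#' Simulates replicate case-control studies from a logistic model with PM
#' and EHE main effects but no product term, fits the full and reduced
#' adjusted models to each, and reports the fraction of replicates whose
#' LRT p-value falls below `alpha`. Under a correctly calibrated test this
#' fraction equals the nominal level up to binomial Monte-Carlo error.
#'
#' @param n_reps number of replicate studies.
#' @param n_cases,n_controls size of each study.
#' @param model generating [true_model()]; its `beta_interaction` should be
#'   0 for a null calibration (the default is the package's null model:
#'   OR 1.3 for high PM, 1.2 for EHE, modest covariate effects).
#' @param alpha nominal test level (default 0.1, the study convention).
#' @param seed integer seed for the whole simulation.
#' @return list: `rejection_rate`, `n_reps`, `alpha`, `p_values`.
#' @export
lrt_calibration <- function(n_reps = 1000L, n_cases = 1500L,
                            n_controls = 1500L,
                            model = true_model(
                              stats::qlogis(0.08),
                              beta_pm = log(1.3), beta_ehe = log(1.2),
                              beta_interaction = 0,
                              covariate_betas = list(
                                maternal_age_cat = c("<=19" = 0.10,
                                                     ">=35" = 0.15),
                                education_cat = c("<12y" = 0.10),
                                race_ethnicity = c("NH-black" = 0.10,
                                                   "Hispanic" = 0.05)),
                              beta_dew_point = 0.01),
                            alpha = 0.1, seed = 1L) {
  stopifnot(model$beta_interaction == 0 || alpha > 0)
  set.seed(seed)
  spec <- design_spec("VSDpm", "full", model$ehe_definition)
  pvals <- vapply(seq_len(n_reps), function(r) {
    d <- simulate_cc_study(n_cases, n_controls, model)
    des <- build_design(d, spec, "product_term")
    fit_full <- fit_logistic(des$X, des$y)
    fit_red <- fit_logistic(
      des$X[, colnames(des$X) != des$cols$interaction, drop = FALSE], des$y)
    lrt_interaction(fit_full, fit_red)$p_value
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), n_reps = n_reps, alpha = alpha,
       p_values = pvals)
}

#' Coverage of the profile-likelihood RERI confidence interval
#'
#' Simulates replicate case-control studies from a joint-4-level logistic
#' model with a known true RERI, computes the profile-likelihood interval
#' in each, and reports the fraction of intervals containing the truth.
#'
#' @param n_reps number of replicate studies.
#' @param n_cases,n_controls size of each study.
#' @param model generating [true_model()]; the default implies joint odds
#'   ratios (OR10, OR01, OR11) = (1.5, 1.3, 2.3), i.e. true RERI = 0.5.
#' @param level nominal confidence level (default 0.95).
#' @param seed integer seed for the whole simulation.
#' @return list: `coverage` (fraction in `[0, 1]`), `n_reps`, `true_reri`,
#'   `n_profile_ok` (replicates where both endpoints met the deviance
#'   condition), `estimates` (per-replicate RERI point estimates).
#' @export
reri_coverage <- function(n_reps = 500L, n_cases = 2000L,
                          n_controls = 2000L,
                          model = true_model(
                            stats::qlogis(0.08),
                            beta_pm = log(1.5), beta_ehe = log(1.3),
                            beta_interaction = log(2.3) - log(1.5) - log(1.3),
                            covariate_betas = list(
                              maternal_age_cat = c("<=19" = 0.10,
                                                   ">=35" = 0.15),
                              education_cat = c("<12y" = 0.10),
                              race_ethnicity = c("NH-black" = 0.10,
                                                 "Hispanic" = 0.05)),
                            beta_dew_point = 0.01),
                          level = 0.95, seed = 1L) {
  set.seed(seed)
  spec <- design_spec("VSDpm", "full", model$ehe_definition)
  truth <- model$true_reri
  covered <- logical(n_reps)
  ok <- logical(n_reps)
  est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    d <- simulate_cc_study(n_cases, n_controls, model)
    des <- build_design(d, spec, "joint_4level")
    fit <- fit_logistic(des$X, des$y)
    prof <- reri_ci_profile(des$X, des$y, level = level, fit = fit)
    est[r] <- prof$estimate
    ok[r] <- prof$status_lower == "ok" && prof$status_upper == "ok"
    covered[r] <- isTRUE(prof$lower <= truth && prof$upper >= truth)
  }
  list(coverage = mean(covered), n_reps = n_reps, true_reri = truth,
       n_profile_ok = sum(ok), estimates = est)
}

#' Parameter recovery on a large synthetic cohort
#'
#' Simulates one large cohort from a model with a known effect-measure
#' modification pattern, fits both interaction codings to the full cohort,
#' and returns fitted stratum odds ratios and RERI next to their generating
#' values.
#'
#' @param n_cohort cohort size.
#' @param model generating [true_model()]; the default has no PM effect
#'   without heat (OR 1.0) and OR 1.6 for PM under an EHE.
#' @param seed integer seed.
#' @return list: `or_pm_no_ehe`, `or_pm_ehe`, `reri` (fitted), and
#'   `true_or_pm_no_ehe`, `true_or_pm_ehe`, `true_reri`.
#' @export
parameter_recovery <- function(n_cohort = 200000L,
                               model = true_model(
                                 stats::qlogis(0.08),
                                 beta_pm = 0, beta_ehe = log(1.2),
                                 beta_interaction = log(1.6),
                                 covariate_betas = list(
                                   maternal_age_cat = c("<=19" = 0.10,
                                                        ">=35" = 0.15),
                                   education_cat = c("<12y" = 0.10),
                                   race_ethnicity = c("NH-black" = 0.10,
                                                      "Hispanic" = 0.05)),
                                 beta_dew_point = 0.01),
                               seed = 1L) {
  d <- simulate_cohort(n_cohort, model, seed = seed)
  spec <- design_spec("VSDpm", "full", model$ehe_definition)
  desp <- build_design(d, spec, "product_term")
  fitp <- fit_logistic(desp$X, desp$y)
  ors <- stratum_ors(fitp, desp$cols)
  desj <- build_design(d, spec, "joint_4level")
  fitj <- fit_logistic(desj$X, desj$y)
  b <- fitj$coefficients
  reri <- reri_point(exp(b[["joint11"]]), exp(b[["joint10"]]),
                     exp(b[["joint01"]]))
  list(or_pm_no_ehe = ors$or_pm_no_ehe[["or"]],
       or_pm_ehe = ors$or_pm_ehe[["or"]], reri = reri,
       true_or_pm_no_ehe = model$true_or10,
       true_or_pm_ehe = exp(model$beta_pm + model$beta_interaction),
       true_reri = model$true_reri)
}
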