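#' Run the full interaction analysis grid
#'
#' One multiplicative and one additive interaction model per
#' (outcome group x population filter x EHE definition) cell, returned as a
#' tidy table with one row per reported quantity. Per-cell failures are
#' caught and recorded as status codes rather than aborting the grid.
#'
#' @param data merged subject/exposure table.
#' @param outcome_groups character vector of case outcome groups.
#' @param ehe_definitions character vector among `"EHE95"`, `"EHE90"`.
#' @param population_filters character vector among `"full"`,
#'   `"any_spring_summer"`, `"entire_spring_summer"`, `"any_summer"`.
#' @param alpha LRT level for the effect-measure-modification flag
#'   (default 0.1).
#' @param level confidence level for all intervals (default 0.95).
#' @param profile_ci compute profile-likelihood RERI intervals
#'   (default TRUE).
#' @return tibble with columns `outcome_group`, `population_filter`,
#'   `ehe_definition`, `scale`, `term`, `estimate`, `conf_low`,
#'   `conf_high`, `ci_method`, `statistic`, `p_value`, `n_cases`,
#'   `n_controls`, `n_dropped`, `status`.
#' @export
run_analysis <- function(data, outcome_groups,
                         ehe_definitions = c("EHE95", "EHE90"),
                         population_filters = c("full", "any_spring_summer",
                                                "entire_spring_summer",
                                                "any_summer"),
                         alpha = 0.1, level = 0.95, profile_ci = TRUE) {
  row <- function(og, fl, def, scale, term, estimate = NA_real_,
                  conf_low = NA_real_, conf_high = NA_real_,
                  ci_method = NA_character_, statistic = NA_real_,
                  p_value = NA_real_, n_cases = NA_integer_,
                  n_controls = NA_integer_, n_dropped = NA_integer_,
                  status = "ok") {
    tibble::tibble(outcome_group = og, population_filter = fl,
                   ehe_definition = def, scale = scale, term = term,
                   estimate = estimate, conf_low = conf_low,
                   conf_high = conf_high, ci_method = ci_method,
                   statistic = statistic, p_value = p_value,
                   n_cases = n_cases, n_controls = n_controls,
                   n_dropped = n_dropped, status = status)
  }

  out <- list()
  for (og in outcome_groups) for (fl in population_filters)
    for (def in ehe_definitions) {
      spec <- design_spec(og, fl, def)
      mult <- tryCatch(
        multiplicative_interaction(data, spec, alpha, level),
        error = function(e) e)
      if (inherits(mult, "error")) {
        out[[length(out) + 1]] <- row(og, fl, def, "multiplicative", "error",
                                      status = conditionMessage(mult))
      } else {
        out[[length(out) + 1]] <- dplyr::bind_rows(
          row(og, fl, def, "multiplicative", "or_pm_no_ehe",
              mult$or_pm_no_ehe[["or"]], mult$or_pm_no_ehe[["lower"]],
              mult$or_pm_no_ehe[["upper"]], "wald",
              n_cases = mult$n_cases, n_controls = mult$n_controls,
              n_dropped = mult$n_dropped, status = mult$status),
          row(og, fl, def, "multiplicative", "or_pm_ehe",
              mult$or_pm_ehe[["or"]], mult$or_pm_ehe[["lower"]],
              mult$or_pm_ehe[["upper"]], "wald",
              n_cases = mult$n_cases, n_controls = mult$n_controls,
              n_dropped = mult$n_dropped, status = mult$status),
          row(og, fl, def, "multiplicative", "lrt_interaction",
              statistic = mult$lrt_statistic, p_value = mult$lrt_p,
              n_cases = mult$n_cases, n_controls = mult$n_controls,
              n_dropped = mult$n_dropped, status = mult$status)
        )
      }
      add <- tryCatch(
        additive_interaction(data, spec, level, profile_ci),
        error = function(e) e)
      if (inherits(add, "error")) {
        out[[length(out) + 1]] <- row(og, fl, def, "additive", "error",
                                      status = conditionMessage(add))
      } else {
        rows <- list(
          row(og, fl, def, "additive", "or10", add$or10[["or"]],
              add$or10[["lower"]], add$or10[["upper"]], "wald",
              n_cases = add$n_cases, n_controls = add$n_controls,
              n_dropped = add$n_dropped, status = add$status),
          row(og, fl, def, "additive", "or01", add$or01[["or"]],
              add$or01[["lower"]], add$or01[["upper"]], "wald",
              n_cases = add$n_cases, n_controls = add$n_controls,
              n_dropped = add$n_dropped, status = add$status),
          row(og, fl, def, "additive", "or11", add$or11[["or"]],
              add$or11[["lower"]], add$or11[["upper"]], "wald",
              n_cases = add$n_cases, n_controls = add$n_controls,
              n_dropped = add$n_dropped, status = add$status),
          row(og, fl, def, "additive", "reri", add$reri,
              add$reri_ci_delta$lower, add$reri_ci_delta$upper, "delta",
              n_cases = add$n_cases, n_controls = add$n_controls,
              n_dropped = add$n_dropped, status = add$status)
        )
        if (!is.null(add$reri_ci_likelihood)) {
          pc <- add$reri_ci_likelihood
          rows[[length(rows) + 1]] <- row(
            og, fl, def, "additive", "reri", add$reri, pc$lower, pc$upper,
            "profile_likelihood",
            n_cases = add$n_cases, n_controls = add$n_controls,
            n_dropped = add$n_dropped,
            status = paste(add$status,
                           paste0(pc$status_lower, "/", pc$status_upper),
                           sep = ";"))
        }
        out[[length(out) + 1]] <- dplyr::bind_rows(rows)
      }
    }
  dplyr::bind_rows(out)
}
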