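#' Analysis design specification
#'
#' One model cell of the analysis: an outcome group, a population filter,
#' and a heat-event metric. The adjustment set is fixed — maternal age,
#' maternal education, race/ethnicity and window-mean dew point — and the
#' full-population model is additionally adjusted for an indicator of
#' having at least one window day in spring or summer.
#'
#' @param outcome_group outcome-group label of the cases (controls are
#'   always `"control"`).
#' @param population_filter which subjects enter the model: everyone
#'   (`"full"`), at least one window day in spring/summer
#'   (`"any_spring_summer"`), entire window in spring/summer
#'   (`"entire_spring_summer"`), or at least one summer day
#'   (`"any_summer"`).
#' @param ehe_definition `"EHE95"` or `"EHE90"`.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(outcome_group,
                        population_filter = c("full", "any_spring_summer",
                                              "entire_spring_summer",
                                              "any_summer"),
                        ehe_definition = c("EHE95", "EHE90")) {
  structure(list(outcome_group = outcome_group,
                 population_filter = match.arg(population_filter),
                 ehe_definition = match.arg(ehe_definition),
                 adjustment = c("maternal_age_cat", "education_cat",
                                "race_ethnicity", "mean_dew_point")),
            class = "design_spec")
}

.factor_ref <- function(x, ref) {
  lev <- unique(as.character(x))
  if (ref %in% lev) lev <- c(ref, setdiff(lev, ref))
  factor(as.character(x), levels = lev)
}

#' Build the design matrix and outcome vector for one model cell
#'
#' Selects cases of the design's outcome group plus controls, applies the
#' population filter, drops rows with missing exposures or covariates
#' (complete-case), and reference-codes the exposures. Under
#' `coding = "product_term"` the exposure columns are `pm`, `ehe` and their
#' elementwise product `pm:ehe`; under `coding = "joint_4level"` they are
#' indicators `joint10` (high PM only), `joint01` (EHE only) and `joint11`
#' (both), with low-PM/no-EHE as the joint reference. Covariate references:
#' age 20-34, education >=12y, NH-white.
#'
#' @param data merged subject/exposure table (one row per subject).
#' @param spec a [design_spec()].
#' @param coding `"product_term"` or `"joint_4level"`.
#' @return list: `X` (model matrix), `y` (0/1 outcome), `n_cases`,
#'   `n_controls`, `n_dropped` (complete-case exclusions), `cols` (names of
#'   the exposure columns in `X`), `empty_cells` (joint-coding cells with no
#'   observation — the model is still attempted, CIs will be degenerate),
#'   `data` (the analysis rows used).
#' @export
build_design <- function(data, spec, coding = c("product_term",
                                                "joint_4level")) {
  coding <- match.arg(coding)
  stopifnot(inherits(spec, "design_spec"))
  ehe_col <- paste0(tolower(spec$ehe_definition), "_exposed")
  need <- c("pm_high", ehe_col, spec$adjustment)
  if (spec$population_filter == "full") need <- c(need, "any_day_spring_summer")
  miss <- setdiff(c(need, "is_case", "outcome_group"), names(data))
  if (length(miss) > 0) {
    stop("data is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  df <- data[data$outcome_group %in% c(spec$outcome_group, "control"), ,
             drop = FALSE]
  df <- switch(spec$population_filter,
    full = df,
    any_spring_summer = df[df$any_day_spring_summer %in% TRUE, , drop = FALSE],
    entire_spring_summer = df[df$entire_window_spring_summer %in% TRUE, ,
                              drop = FALSE],
    any_summer = df[df$any_day_summer %in% TRUE, , drop = FALSE])

  cc <- stats::complete.cases(df[, need, drop = FALSE])
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) == 0 || sum(df$is_case) == 0 || sum(!df$is_case) == 0) {
    stop("analytic population has no cases or no controls after filtering",
         call. = FALSE)
  }

  mf <- data.frame(
    pm = as.numeric(df$pm_high),
    ehe = as.numeric(df[[ehe_col]]),
    maternal_age_cat = .factor_ref(df$maternal_age_cat, "20-34"),
    education_cat = .factor_ref(df$education_cat, ">=12y"),
    race_ethnicity = .factor_ref(df$race_ethnicity, "NH-white"),
    mean_dew_point = df$mean_dew_point
  )
  rhs <- "maternal_age_cat + education_cat + race_ethnicity + mean_dew_point"
  if (spec$population_filter == "full") {
    mf$spring_summer <- as.numeric(df$any_day_spring_summer)
    rhs <- paste(rhs, "+ spring_summer")
  }

  empty_cells <- character(0)
  if (coding == "product_term") {
    fml <- stats::as.formula(paste("~ pm * ehe +", rhs))
    cols <- list(pm = "pm", ehe = "ehe", interaction = "pm:ehe")
  } else {
    mf$joint <- factor(paste0(mf$pm, mf$ehe),
                       levels = c("00", "10", "01", "11"))
    tab <- table(mf$joint)
    empty_cells <- names(tab)[tab == 0]
    if (length(empty_cells) > 0) {
      warning("empty joint-exposure cell(s): ",
              paste0("joint", empty_cells, collapse = ", "),
              "; model attempted, expect undefined/degenerate CIs",
              call. = FALSE)
    }
    fml <- stats::as.formula(paste("~ joint +", rhs))
    cols <- list(or10 = "joint10", or01 = "joint01", or11 = "joint11")
  }
  X <- stats::model.matrix(fml, mf)
  list(X = X, y = as.integer(df$is_case), n_cases = sum(df$is_case),
       n_controls = sum(!df$is_case), n_dropped = n_dropped, cols = cols,
       empty_cells = empty_cells, data = df)
}

# Numerically stable Bernoulli log-likelihood at linear predictor eta.
.binom_ll <- function(eta, y) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares (via `stats::glm.fit`), with
#' convergence declared when the relative deviance change drops below
#' `tol`. Perfect or quasi-perfect separation is detected through boundary
#' fits and diverging coefficient norms; the fit is then flagged
#' `converged = FALSE` and downstream consumers refuse to interpret it.
#'
#' @param X design matrix (including intercept column).
#' @param y 0/1 outcome vector.
#' @param tol relative convergence tolerance (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return object of class `logistic_fit`: `coefficients`, `vcov`
#'   (inverse observed information), `log_likelihood`, `converged`,
#'   `n_used`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least 1 case and 1 control", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = tol, maxit = max_iter))
  )
  p <- fit$rank
  coefs <- fit$coefficients
  Qr <- fit$qr
  vcov <- matrix(NA_real_, ncol(X), ncol(X),
                 dimnames = list(colnames(X), colnames(X)))
  covmat <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  vcov[Qr$pivot[seq_len(p)], Qr$pivot[seq_len(p)]] <- covmat
  eta <- drop(X %*% ifelse(is.na(coefs), 0, coefs))
  converged <- isTRUE(fit$converged) && !anyNA(coefs) &&
    max(abs(coefs)) < 15 && !isTRUE(fit$boundary)
  structure(list(coefficients = coefs, vcov = vcov,
                 log_likelihood = .binom_ll(eta, y),
                 converged = converged, n_used = nrow(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit: n =", x$n_used,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test for the interaction term
#'
#' `statistic = 2 * (ll_full - ll_reduced)`, referred to chi-square with
#' 1 degree of freedom (the models differ by the single product term).
#'
#' @param fit_full,fit_reduced nested [fit_logistic()] fits (full has
#'   exactly one more parameter).
#' @return list `statistic`, `p_value`, `df`.
#' @export
lrt_interaction <- function(fit_full, fit_reduced) {
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  if (df != 1) {
    stop("models must differ by exactly the single product term", call. = FALSE)
  }
  stat <- 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood)
  if (stat < -1e-6) {
    stop("negative LRT statistic (", format(stat),
         "): fits are non-nested or not converged", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Stratum-specific PM2.5 odds ratios from a product-term fit
#'
#' Within each stratum of EHE exposure the reference is low PM2.5:
#' `OR(PM | no EHE) = exp(beta_pm)` with a Wald CI from `var(beta_pm)`, and
#' `OR(PM | EHE) = exp(beta_pm + beta_int)` with
#' `var = var(beta_pm) + var(beta_int) + 2 cov`.
#'
#' @param fit converged product-term [fit_logistic()].
#' @param cols names of the pm/ehe/interaction columns (as produced by
#'   [build_design()]).
#' @param level confidence level (default 0.95).
#' @return list with `or_pm_no_ehe` and `or_pm_ehe`, each
#'   `c(or, lower, upper)`.
#' @export
stratum_ors <- function(fit, cols = list(pm = "pm", ehe = "ehe",
                                         interaction = "pm:ehe"),
                        level = 0.95) {
  if (!fit$converged) {
    stop("refusing to compute stratum ORs from a non-converged fit",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  V <- fit$vcov
  bpm <- b[[cols$pm]]
  bint <- b[[cols$interaction]]
  se0 <- sqrt(V[cols$pm, cols$pm])
  se1 <- sqrt(V[cols$pm, cols$pm] + V[cols$interaction, cols$interaction] +
                2 * V[cols$pm, cols$interaction])
  list(
    or_pm_no_ehe = c(or = exp(bpm), lower = exp(bpm - z * se0),
                     upper = exp(bpm + z * se0)),
    or_pm_ehe = c(or = exp(bpm + bint), lower = exp(bpm + bint - z * se1),
                  upper = exp(bpm + bint + z * se1))
  )
}

#' Multiplicative-scale interaction analysis for one model cell
#'
#' Fits the adjusted product-term logistic model and its main-effects
#' reduction, runs the likelihood-ratio test for effect-measure
#' modification at `alpha` (the study convention is 0.1, trading type-I
#' error for power to detect interaction), and reports stratum-specific
#' PM2.5 odds ratios.
#'
#' @param data merged subject/exposure table.
#' @param spec a [design_spec()].
#' @param alpha LRT significance level for the modification flag.
#' @param level confidence level for the odds-ratio CIs.
#' @return list of class `multiplicative_result`: stratum ORs with CIs,
#'   `lrt_statistic`, `lrt_p`, `modification_flag`, counts, `status`.
#' @export
multiplicative_interaction <- function(data, spec, alpha = 0.1,
                                       level = 0.95) {
  des <- build_design(data, spec, coding = "product_term")
  fit_full <- fit_logistic(des$X, des$y)
  fit_red <- fit_logistic(des$X[, colnames(des$X) != des$cols$interaction,
                                drop = FALSE], des$y)
  status <- if (fit_full$converged && fit_red$converged) "ok" else
    "not_converged"
  ors <- if (status == "ok") stratum_ors(fit_full, des$cols, level) else
    list(or_pm_no_ehe = c(or = NA_real_, lower = NA_real_, upper = NA_real_),
         or_pm_ehe = c(or = NA_real_, lower = NA_real_, upper = NA_real_))
  lrt <- if (status == "ok") lrt_interaction(fit_full, fit_red) else
    list(statistic = NA_real_, p_value = NA_real_, df = 1L)
  structure(list(
    spec = spec, or_pm_no_ehe = ors$or_pm_no_ehe, or_pm_ehe = ors$or_pm_ehe,
    lrt_statistic = lrt$statistic, lrt_p = lrt$p_value,
    modification_flag = isTRUE(lrt$p_value < alpha), alpha = alpha,
    n_cases = des$n_cases, n_controls = des$n_controls,
    n_dropped = des$n_dropped, status = status, fit = fit_full
  ), class = "multiplicative_result")
}
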