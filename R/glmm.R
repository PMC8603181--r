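# Group-difference analysis: per-biomarker mixed models with crossed random
# effects, likelihood-ratio test for the MCI effect, marginal/conditional
# R-squared, and the assembled per-biomarker results table.
#
# Model fitting is delegated to lme4 (maximum likelihood throughout, never
# REML, so that full and reduced models are comparable in the LRT); the LRT
# arithmetic and the R-squared decomposition are computed here.

glmm_formula <- function(outcome, with_mci = TRUE, random_slope = TRUE) {
  fixed <- if (with_mci) {
    "mci + age + tablet_proficiency + game_proficiency"
  } else {
    "age + tablet_proficiency + game_proficiency"
  }
  rand <- "(1 | participant_id) + (1 | seed)"
  if (random_slope) rand <- paste(rand, "+ (0 + mci | participant_id)")
  stats::as.formula(paste0("`", outcome, "` ~ ", fixed, " + ", rand))
}

prepare_model_data <- function(data, outcome) {
  need <- c(outcome, "mci", "age", "tablet_proficiency", "game_proficiency",
            "participant_id", "seed")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop(sprintf("analysis table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d <- data[need]
  if (is.logical(d[[outcome]])) d[[outcome]] <- as.integer(d[[outcome]])
  keep <- !is.na(d[[outcome]])
  list(data = d[keep, ], n_dropped = sum(!keep))
}

#' Fit the per-biomarker mixed model
#'
#' Fits the specified crossed-random-effects model for one biomarker by
#' maximum likelihood: fixed effects for MCI, age, tablet proficiency and
#' game proficiency (proficiency ordinals entered as numeric 0..4); random
#' intercepts per participant and per game seed; and, by default, a
#' by-participant random slope for MCI. Because MCI does not vary within a
#' participant, that slope acts as group-specific participant variance and
#' is only weakly identified; when the fit is singular and
#' `drop_slope_if_singular = TRUE` the model is refitted without it (the
#' fallback is recorded). Continuous biomarkers use the identity link
#' (linear mixed model); binary ones a mixed logistic model. Rows with an
#' undefined (NA) outcome are dropped and counted.
#'
#' @param data Analysis table from [cohort_table()] or
#'   [generate_from_glmm()].
#' @param outcome Biomarker column to model.
#' @param link `"identity"` or `"logit"`; default looked up in
#'   [biomarker_registry()], falling back to identity.
#' @param random_slope Include the by-participant MCI slope. Default (`NULL`):
#'   TRUE for identity links, FALSE for logit links -- with a binary outcome
#'   and few games per participant the slope's likelihood is maximized at
#'   degenerate values that drag the MCI coefficient along (see the methods
#'   vignette); pass `TRUE` to force the literal model.
#' @param drop_slope_if_singular Refit without the slope on a singular fit.
#' @param with_mci Include the MCI fixed effect (the reduced model of the
#'   likelihood-ratio test sets this to FALSE).
#' @return A `glmm_fit` object (use [tidy()] / [glance()]).
#' @export
fit_biomarker_glmm <- function(data, outcome, link = NULL,
                               random_slope = NULL,
                               drop_slope_if_singular = TRUE,
                               with_mci = TRUE) {
  if (is.null(link)) {
    reg <- biomarker_registry()
    link <- if (outcome %in% reg$biomarker) {
      reg$link[reg$biomarker == outcome]
    } else "identity"
  }
  link <- match.arg(link, c("identity", "logit"))
  if (is.null(random_slope)) random_slope <- link == "identity"
  prep <- prepare_model_data(data, outcome)
  d <- prep$data
  if (length(unique(d$participant_id[d$mci == 1])) < 2 ||
      length(unique(d$participant_id[d$mci == 0])) < 2) {
    if (with_mci && length(unique(d$mci)) > 1) {
      stop("need at least 2 participants per group", call. = FALSE)
    }
  }
  do_fit <- function(slope) {
    fml <- glmm_formula(outcome, with_mci = with_mci, random_slope = slope)
    suppressMessages(
      if (link == "identity") {
        lme4::lmer(fml, data = d, REML = FALSE)
      } else {
        lme4::glmer(fml, data = d, family = stats::binomial())
      }
    )
  }
  slope_used <- random_slope
  fit <- tryCatch(do_fit(random_slope), error = function(e) {
    stop(sprintf("mixed-model fit failed for '%s': %s", outcome,
                 conditionMessage(e)), call. = FALSE)
  })
  singular <- lme4::isSingular(fit)
  slope_dropped <- FALSE
  if (singular && random_slope && drop_slope_if_singular) {
    refit <- tryCatch(do_fit(FALSE), error = function(e) NULL)
    if (!is.null(refit)) {
      fit <- refit
      slope_used <- FALSE
      slope_dropped <- TRUE
      singular <- lme4::isSingular(fit)
    }
  }
  structure(list(fit = fit, outcome = outcome, link = link,
                 with_mci = with_mci, random_slope = slope_used,
                 slope_dropped = slope_dropped, singular = singular,
                 n_dropped = prep$n_dropped, n_obs = nrow(d)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s (%s link), %d obs (%d dropped)%s%s\n",
              x$outcome, x$link, x$n_obs, x$n_dropped,
              if (x$singular) ", singular" else "",
              if (x$slope_dropped) ", MCI slope dropped" else ""))
  print(summary(x$fit)$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a fitted biomarker model
#'
#' @param x A `glmm_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`.
#' @export
tidy.glmm_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, "Estimate"]),
                 std_error = unname(co[, "Std. Error"]),
                 statistic = unname(co[, 3]))
}

#' One-row model summary
#'
#' @param x A `glmm_fit`.
#' @param ... Unused.
#' @export
glance.glmm_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, link = x$link, n_obs = x$n_obs,
                 n_dropped = x$n_dropped,
                 log_lik = as.numeric(stats::logLik(x$fit)),
                 aic = stats::AIC(x$fit), singular = x$singular,
                 slope_dropped = x$slope_dropped)
}

#' Likelihood-ratio test for the MCI effect
#'
#' Compares the model for a biomarker with the model without the MCI fixed
#' effect (identical random structure, including the by-participant MCI
#' slope), both estimated by maximum likelihood without REML:
#' `chi2 = 2 (llf_full - llf_reduced)` on 1 degree of freedom.
#'
#' @inheritParams fit_biomarker_glmm
#' @return An `lrt_result`: list with `chi2`, `df`, `p_value` and the two
#'   `glmm_fit`s.
#' @export
lrt_mci <- function(data, outcome, link = NULL, random_slope = NULL,
                    drop_slope_if_singular = TRUE) {
  full <- tryCatch(
    fit_biomarker_glmm(data, outcome, link = link,
                       random_slope = random_slope,
                       drop_slope_if_singular = drop_slope_if_singular),
    error = function(e) stop(sprintf("full model failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  reduced <- tryCatch(
    fit_biomarker_glmm(data, outcome, link = link,
                       random_slope = full$random_slope,
                       drop_slope_if_singular = drop_slope_if_singular,
                       with_mci = FALSE),
    error = function(e) stop(sprintf("reduced model failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(full$fit)) -
                        as.numeric(stats::logLik(reduced$fit))))
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 fit_full = full, fit_reduced = reduced),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT for MCI on '%s': chi2(1) = %.3f, p = %.4g\n",
              x$fit_full$outcome, x$chi2, x$p_value))
  invisible(x)
}

#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(outcome = x$fit_full$outcome, chi2 = x$chi2, df = x$df,
                 p_value = x$p_value)
}

# the variance-decomposition identity, shared by r2_nakagawa and its tests
r2_from_components <- function(var_fixed, var_random, var_dist) {
  total <- var_fixed + var_random + var_dist
  if (total <= 0) stop("undefined R-squared: zero total variance", call. = FALSE)
  tibble::tibble(r2_marginal = var_fixed / total,
                 r2_conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition R-squared: the marginal value is the share of
#' variance explained by the fixed effects,
#' `var_f / (var_f + var_random + var_dist)`, and the conditional value adds
#' the random-effect variance to the numerator. `var_f` is the variance of
#' the fixed-effect linear predictor over the data, `var_random` the sum of
#' the random-effect variance components, and `var_dist` the residual
#' variance (identity link) or `pi^2 / 3` (logit link).
#'
#' @param fit A `glmm_fit`.
#' @return Tibble with `r2_marginal` and `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  m <- fit$fit
  X <- stats::model.matrix(m)
  beta <- lme4::fixef(m)
  var_fixed <- stats::var(as.vector(X %*% beta))
  vc <- lme4::VarCorr(m)
  var_random <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_dist <- if (fit$link == "identity") stats::sigma(m)^2 else pi^2 / 3
  r2_from_components(var_fixed, var_random, var_dist)
}

#' Per-biomarker results table
#'
#' Fits the specified mixed model for every registry biomarker present in
#' the analysis table and assembles one row per biomarker: intercept and
#' MCI coefficient with standard errors, the likelihood-ratio chi-squared
#' and p value, and marginal/conditional R-squared, grouped by category in
#' registry order. A failure for one biomarker is recorded in its row
#' (`error` column) and does not abort the others.
#'
#' @inheritParams fit_biomarker_glmm
#' @param biomarkers Biomarker columns to analyze; defaults to all registry
#'   biomarkers present in `data`.
#' @return A tibble with one row per biomarker.
#' @export
results_table <- function(data, biomarkers = NULL, random_slope = NULL,
                          drop_slope_if_singular = TRUE) {
  reg <- biomarker_registry()
  if (is.null(biomarkers)) {
    biomarkers <- intersect(reg$biomarker, names(data))
  }
  purrr::map_dfr(biomarkers, function(bm) {
    base <- tibble::tibble(
      biomarker = bm,
      category = reg$category[match(bm, reg$biomarker)],
      link = reg$link[match(bm, reg$biomarker)],
      constant = NA_real_, constant_se = NA_real_,
      beta_mci = NA_real_, beta_mci_se = NA_real_,
      chi2 = NA_real_, p_value = NA_real_,
      r2_marginal = NA_real_, r2_conditional = NA_real_,
      n_obs = NA_integer_, n_dropped = NA_integer_,
      singular = NA, error = NA_character_
    )
    tryCatch({
      lrt <- lrt_mci(data, bm, random_slope = random_slope,
                     drop_slope_if_singular = drop_slope_if_singular)
      fit <- lrt$fit_full
      td <- tidy(fit)
      r2 <- r2_nakagawa(fit)
      base$constant <- td$estimate[td$term == "(Intercept)"]
      base$constant_se <- td$std_error[td$term == "(Intercept)"]
      base$beta_mci <- td$estimate[td$term == "mci"]
      base$beta_mci_se <- td$std_error[td$term == "mci"]
      base$chi2 <- lrt$chi2
      base$p_value <- lrt$p_value
      base$r2_marginal <- r2$r2_marginal
      base$r2_conditional <- r2$r2_conditional
      base$n_obs <- fit$n_obs
      base$n_dropped <- fit$n_dropped
      base$singular <- fit$singular
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  })
}

#' Significance filter over a results table
#'
#' Retains rows with `p_value < alpha` (strictly below; no multiplicity
#' correction is applied, matching the exploratory single-test design).
#'
#' @param results A results tibble with a `p_value` column (from
#'   [results_table()] or [reference_results()]).
#' @param alpha Significance level.
#' @return A list with `retained` (the filtered tibble) and `n_retained`.
#' @examples
#' significance_filter(reference_results(), 0.05)$n_retained  # 12
#' @export
significance_filter <- function(results, alpha = 0.05) {
  stopifnot("p_value" %in% names(results), alpha >= 0)
  retained <- dplyr::filter(results, !is.na(.data$p_value),
                            .data$p_value < alpha)
  list(retained = retained, n_retained = nrow(retained), alpha = alpha)
}
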