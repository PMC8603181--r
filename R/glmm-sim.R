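# Model-based synthetic biomarker tables.
#
# Draws per-game biomarker values directly from the generative structure of
# the group-difference model: fixed effects for group, age and the two
# proficiency ordinals; Gaussian random intercepts per participant and per
# game seed plus a by-participant MCI slope; identity link with Gaussian
# residual or logit link with Bernoulli outcome. Published coefficients can
# be planted as ground truth for parameter-recovery simulations.

#' Generative model specification for one biomarker
#'
#' @param outcome Biomarker (outcome column) name.
#' @param link `"identity"` or `"logit"`.
#' @param constant Intercept.
#' @param beta_mci Fixed effect of group membership (MCI = 1).
#' @param beta_age,beta_tablet,beta_game Fixed effects of age (years) and of
#'   the tablet / game proficiency ordinals (0..4). Default 0: the published
#'   table reports only the intercept and the MCI coefficient.
#' @param sd_participant,sd_seed SDs of the random intercepts.
#' @param sd_slope_mci SD of the by-participant MCI slope.
#' @param sd_residual Residual SD (identity link only).
#' @return A `glmm_gen_spec` object.
#' @export
glmm_generator_spec <- function(outcome, link = c("identity", "logit"),
                                constant = 0, beta_mci = 0, beta_age = 0,
                                beta_tablet = 0, beta_game = 0,
                                sd_participant = 1, sd_seed = 0.5,
                                sd_slope_mci = 0, sd_residual = 1) {
  link <- match.arg(link)
  stopifnot(sd_participant >= 0, sd_seed >= 0, sd_slope_mci >= 0,
            sd_residual >= 0)
  structure(list(outcome = outcome, link = link, constant = constant,
                 beta_mci = beta_mci, beta_age = beta_age,
                 beta_tablet = beta_tablet, beta_game = beta_game,
                 sd_participant = sd_participant, sd_seed = sd_seed,
                 sd_slope_mci = sd_slope_mci, sd_residual = sd_residual),
            class = "glmm_gen_spec")
}

#' Plant a published biomarker row as generator truth
#'
#' Builds a [glmm_generator_spec()] from the published results row of a
#' biomarker. Variance components are not published; for identity-link rows
#' they are calibrated from the row's reported marginal/conditional
#' R-squared under the variance decomposition used by [r2_nakagawa()]
#' (fixed-effect variance `beta_mci^2 / 4` for a balanced two-group design,
#' total = fixed / R2m, random = total * (R2c - R2m), residual =
#' total * (1 - R2c)), with the random share split
#' participant : seed : slope = 70 : 20 : 10. The two logit rows report
#' R2c < R2m, which is inconsistent with that decomposition, so logit rows
#' use fixed defaults (participant 1, seed 0.25, slope 0.25 on the
#' log-odds scale) under which participant variance still dominates.
#'
#' @param biomarker A biomarker name from [biomarker_registry()].
#' @return A `glmm_gen_spec`.
#' @export
spec_from_reference <- function(biomarker) {
  row <- reference_results()[reference_results()$biomarker == biomarker, ]
  if (!nrow(row)) stop(sprintf("unknown biomarker '%s'", biomarker), call. = FALSE)
  if (row$link == "logit") {
    return(glmm_generator_spec(outcome = biomarker, link = "logit",
                               constant = row$constant, beta_mci = row$beta_mci,
                               sd_participant = 1, sd_seed = 0.5,
                               sd_slope_mci = 0.5, sd_residual = 0))
  }
  var_fixed <- row$beta_mci^2 / 4
  total <- var_fixed / row$r2_marginal
  var_random <- total * (row$r2_conditional - row$r2_marginal)
  var_resid <- total * (1 - row$r2_conditional)
  glmm_generator_spec(outcome = biomarker, link = "identity",
                      constant = row$constant, beta_mci = row$beta_mci,
                      sd_participant = sqrt(0.7 * var_random),
                      sd_seed = sqrt(0.2 * var_random),
                      sd_slope_mci = sqrt(0.1 * var_random),
                      sd_residual = sqrt(var_resid))
}

#' Draw a synthetic analysis table from the generative model
#'
#' Covariates are drawn from the cohort reference distributions
#' ([draw_participants()]); each participant plays `games_per_participant`
#' shared seeds. The linear predictor is
#' `constant + beta_mci*mci + beta_age*age + beta_tablet*tablet +
#' beta_game*game + u_participant + u_seed + u_slope*mci`; the identity link
#' adds Gaussian residual noise, the logit link draws a Bernoulli outcome
#' with probability `plogis(eta)`.
#'
#' @param spec A [glmm_generator_spec()].
#' @param n_per_group Participants per group.
#' @param games_per_participant Games (shared seeds) per participant.
#' @param game_seeds Seed labels; defaults to [default_game_seeds()] values,
#'   recycled/extended as needed.
#' @param rng_seed Master seed; the draw is fully reproducible from it.
#' @return A tibble with one row per participant-game: covariates, `seed`,
#'   `game_index` and the outcome column named `spec$outcome`.
#' @export
generate_from_glmm <- function(spec, n_per_group, games_per_participant = 3,
                               game_seeds = NULL, rng_seed = 1L) {
  stopifnot(inherits(spec, "glmm_gen_spec"), n_per_group >= 1)
  if (is.null(game_seeds)) {
    game_seeds <- default_game_seeds()
    if (games_per_participant > length(game_seeds)) {
      game_seeds <- c(game_seeds,
                      seq(100L, by = 1L,
                          length.out = games_per_participant - length(game_seeds)))
    }
    game_seeds <- game_seeds[seq_len(games_per_participant)]
  }
  stopifnot(length(game_seeds) == games_per_participant)
  with_rng(rng_seed, {
    participants <- dplyr::bind_rows(
      draw_participants(n_per_group, "healthy"),
      draw_participants(n_per_group, "mci")
    )
    participants$mci <- as.integer(participants$group == "mci")
    n <- nrow(participants)
    u_p <- stats::rnorm(n, 0, spec$sd_participant)
    u_slope <- stats::rnorm(n, 0, spec$sd_slope_mci)
    u_s <- stats::rnorm(games_per_participant, 0, spec$sd_seed)
    tab <- tidyr::expand_grid(participants,
                              game_index = seq_len(games_per_participant))
    tab$seed <- game_seeds[tab$game_index]
    idx_p <- rep(seq_len(n), each = games_per_participant)
    eta <- spec$constant + spec$beta_mci * tab$mci + spec$beta_age * tab$age +
      spec$beta_tablet * tab$tablet_proficiency +
      spec$beta_game * tab$game_proficiency +
      u_p[idx_p] + u_slope[idx_p] * tab$mci + u_s[tab$game_index]
    y <- if (spec$link == "identity") {
      eta + stats::rnorm(nrow(tab), 0, spec$sd_residual)
    } else {
      stats::rbinom(nrow(tab), 1L, stats::plogis(eta))
    }
    tab[[spec$outcome]] <- y
    dplyr::relocate(tab, "mci", .after = "group")
  })
}
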