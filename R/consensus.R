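# Expert-rating consensus analysis: summaries of the rating design
# (player actions x cognitive functions, ordinal 0-3 over raters), two-way
# fully crossed consistency ICC from explicit ANOVA mean squares, and the
# conventional reliability bands.

#' Summarize an expert rating design
#'
#' Per (player action, cognitive function) cell: mean and SD of the ratings
#' over raters, with a flag for cells rated at least moderately correlated
#' on average (mean >= 2 on the 0-3 scale).
#'
#' @param ratings Long tibble with columns `rater`, `player_action`,
#'   `cognitive_function`, `rating` (integers 0-3); the design must be fully
#'   crossed (every rater rates every cell).
#' @return A tibble with one row per (player_action, cognitive_function):
#'   `mean`, `sd`, `moderate_or_stronger`.
#' @export
ratings_summary <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  stopifnot(all(c("rater", "player_action", "cognitive_function",
                  "rating") %in% names(ratings)))
  if (any(!ratings$rating %in% 0:3)) {
    stop("ratings must be on the 0-3 scale", call. = FALSE)
  }
  counts <- dplyr::count(ratings, .data$player_action, .data$cognitive_function)
  if (length(unique(counts$n)) > 1L) {
    stop("ragged rating design: every rater must rate every cell", call. = FALSE)
  }
  ratings |>
    dplyr::group_by(.data$player_action, .data$cognitive_function) |>
    dplyr::summarise(mean = mean(.data$rating), sd = stats::sd(.data$rating),
                     .groups = "drop") |>
    dplyr::mutate(moderate_or_stronger = .data$mean >= 2)
}

#' Two-way consistency intraclass correlation
#'
#' ICC for a fully crossed raters-by-targets design, two-way random,
#' type consistency, from the explicit ANOVA decomposition with targets as
#' rows and raters as columns: `ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)`
#' for single measures and `ICC(C,k) = (MS_R - MS_E) / MS_R` for average
#' measures, where `MS_R` is the between-target mean square, `MS_E` the
#' residual (target x rater interaction) mean square and `k` the number of
#' raters. The confidence interval is the standard F-based interval: with
#' `F_obs = MS_R / MS_E` and quantiles of `F(n-1, (n-1)(k-1))`, the average
#' -measures bounds are `1 - 1/F` at `F_obs` divided by the upper/lower
#' quantile, and the single-measures bounds transform those via
#' `icc / (k - (k-1) icc)`.
#'
#' @param x Ratings with raters in rows and rated targets in columns
#'   (matrix or data frame), fully crossed, no missing cells.
#' @param unit `"average"` (default: the consensus of the full panel is the
#'   measurand) or `"single"`.
#' @param conf_level Confidence level for the F-based interval.
#' @return A one-row tibble: `icc`, `lower`, `upper`, `unit`, `n_raters`,
#'   `n_targets`, `band` (reliability label).
#' @export
icc_consistency <- function(x, unit = c("average", "single"),
                            conf_level = 0.95) {
  unit <- match.arg(unit)
  m <- as.matrix(x)
  if (anyNA(m)) stop("design must be fully crossed: missing cells", call. = FALSE)
  k <- nrow(m)   # raters
  n <- ncol(m)   # targets
  if (k < 2 || n < 2) stop("need at least 2 raters and 2 targets", call. = FALSE)
  ratings <- t(m)  # targets in rows for the ANOVA decomposition
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= 0) {
    stop("undefined ICC: no between-target variance", call. = FALSE)
  }
  if (ms_e == 0) {
    est_s <- est_a <- 1
    lo_a <- hi_a <- 1
  } else {
    est_s <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
    est_a <- (ms_r - ms_e) / ms_r
    f_obs <- ms_r / ms_e
    alpha <- 1 - conf_level
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    lo_a <- 1 - 1 / fl
    hi_a <- 1 - 1 / fu
  }
  to_single <- function(a) a / (k - (k - 1) * a)
  if (unit == "average") {
    est <- est_a; lo <- lo_a; hi <- hi_a
  } else {
    est <- est_s; lo <- to_single(lo_a); hi <- to_single(hi_a)
  }
  tibble::tibble(icc = est, lower = lo, upper = hi, unit = unit,
                 n_raters = k, n_targets = n,
                 band = reliability_band(est))
}

#' Reliability band of an ICC
#'
#' Conventional interpretation bands: below 0.5 poor, 0.5 to 0.75 moderate,
#' 0.75 to 0.9 good, 0.9 and above excellent; lower bounds inclusive.
#'
#' @param icc Numeric ICC estimate(s), each at most 1.
#' @return Character vector of band labels.
#' @examples
#' reliability_band(c(0.3, 0.6, 0.75, 0.95))
#' @export
reliability_band <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12))
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Per-action / per-function ICCs over a rating design
#'
#' Computes [icc_consistency()] once per player action (targets = cognitive
#' functions) or once per cognitive function (targets = player actions),
#' mirroring the two orientations of the consensus analysis.
#'
#' @param ratings Long ratings tibble as in [ratings_summary()].
#' @param margin `"player_action"` or `"cognitive_function"`.
#' @inheritParams icc_consistency
#' @return A tibble with one ICC row per margin level.
#' @export
icc_by <- function(ratings, margin = c("player_action", "cognitive_function"),
                   unit = c("average", "single"), conf_level = 0.95) {
  margin <- match.arg(margin)
  unit <- match.arg(unit)
  target <- setdiff(c("player_action", "cognitive_function"), margin)
  ratings |>
    tibble::as_tibble() |>
    dplyr::group_by(.data[[margin]]) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, id_cols = "rater",
                                 names_from = dplyr::all_of(target),
                                 values_from = "rating")
      icc_consistency(as.matrix(wide[, -1]), unit = unit,
                      conf_level = conf_level)
    }) |>
    dplyr::ungroup()
}

#' Simulate an expert rating design
#'
#' Draws a fully crossed ordinal rating table: each (player action,
#' cognitive function) cell has a latent relatedness drawn uniformly, each
#' rater adds a small leniency shift and noise, and the latent value is
#' discretized to the 0-3 scale. Used to exercise the consensus analysis;
#' the published rating data are unavailable.
#'
#' @param n_raters,n_actions,n_functions Design dimensions (study design:
#'   11 raters, 21 actions, 9 functions).
#' @param rater_sd Rater leniency SD on the latent scale.
#' @param noise_sd Residual noise SD on the latent scale.
#' @param rng_seed Reproducibility seed.
#' @return A long ratings tibble for [ratings_summary()] / [icc_by()].
#' @export
simulate_ratings <- function(n_raters = 11, n_actions = 21, n_functions = 9,
                             rater_sd = 0.3, noise_sd = 0.5, rng_seed = 1L) {
  with_rng(rng_seed, {
    cells <- tidyr::expand_grid(player_action = seq_len(n_actions),
                                cognitive_function = seq_len(n_functions))
    cells$latent <- stats::runif(nrow(cells), -0.5, 3.5)
    raters <- tibble::tibble(rater = sprintf("R%02d", seq_len(n_raters)),
                             shift = stats::rnorm(n_raters, 0, rater_sd))
    tidyr::expand_grid(raters, cells) |>
      dplyr::mutate(rating = pmin(3, pmax(0, round(
        .data$latent + .data$shift + stats::rnorm(dplyr::n(), 0, noise_sd))))) |>
      dplyr::select("rater", "player_action", "cognitive_function", "rating")
  })
}
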