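# Published study tables transcribed as package data: the per-biomarker
# mixed-model results (used as planted truths by the model-based generator
# and as input to the significance filter), the cohort covariate
# distributions (used by both generators), and the consensus-design schema.

#' Published mixed-model results per biomarker
#'
#' The reported generalized linear mixed model analysis for each of the 23
#' biomarkers: intercept and MCI coefficient with their standard errors, the
#' likelihood-ratio chi-squared (where reported; missing for the score row),
#' its p value, and marginal/conditional R-squared. These printed values are
#' *inputs*: the underlying raw data are unpublished, so the coefficients
#' serve as planted truths for parameter-recovery simulations
#' ([spec_from_reference()]) and the p values as input to
#' [significance_filter()].
#'
#' @return A 23-row tibble in registry order.
#' @export
reference_results <- function() {
  tibble::tribble(
    ~biomarker,            ~constant,  ~constant_se, ~beta_mci, ~beta_mci_se, ~chi2, ~p_value, ~r2_marginal, ~r2_conditional,
    "think_time_avg",      -1371.778,  1415.444,     1119.947,  405.815,      7.7,   0.006,    0.416,        0.904,
    "think_time_sd",       -814.527,   1720.073,     1112.533,  490.53,       5.1,   0.02,     0.211,        0.655,
    "move_time_avg",       -508.575,   373.89,       156,       95.547,       2.7,   0.1,      0.257,        0.579,
    "move_time_sd",        -856.605,   847.852,      323.599,   202.032,      2.6,   0.1,      0.137,        0.419,
    "total_time_avg",      -912.419,   2149.177,     1278.263,  573.839,      5.2,   0.02,     0.318,        0.870,
    "total_time_sd",       206.569,    2676.062,     1315.598,  673.665,      4.1,   0.04,     0.176,        0.715,
    "final_beta_error",    -7.233,     4.131,        0.435,     0.922,        0.2,   0.65,     0.096,        0.068,
    "beta_error_pct",      -7.203,     33.849,       6.108,     6.879,        0.8,   0.36,     0.089,        0.371,
    "ace_beta_error_pct",  -0.132,     0.629,        0.051,     0.137,        0.1,   0.73,     0.023,        0.209,
    "king_beta_error_pct", -3.682,     5.918,        0.907,     1.323,        0.5,   0.48,     0.028,        0.230,
    "pile_move_pct",       71.759,     24.052,       13.333,    4.88,         7.5,   0.006,    0.097,        0.513,
    "successful_move_pct", 87.486,     9.443,        -8.913,    3.595,        5.9,   0.02,     0.104,        0.795,
    "erroneous_move_pct",  9.486,      6.529,        3.624,     1.651,        4.8,   0.03,     0.081,        0.466,
    "accuracy_avg",        92.134,     9.167,        -3.817,    1.903,        4.1,   0.04,     0.246,        0.805,
    "accuracy_sd",         4.519,      3.746,        0.137,     0.772,        0.04,  0.85,     0.056,        0.196,
    "taps",                -5.113,     10.704,       5.334,     2.762,        3.8,   0.05,     0.098,        0.500,
    "undo_move_pct",       0.228,      0.955,        0.135,     0.205,        0.4,   0.49,     0.008,        0.151,
    "hint_move_pct",       -0.58,      0.87,         -0.311,    0.204,        2.4,   0.12,     0.046,        0.491,
    "game_time",           -167427.7,  187325.5,     93211.27,  53699.25,     3.1,   0.08,     0.198,        0.690,
    "score",               29.03,      1389.752,     -744.433,  286.576,      NA,    0.009,    0.105,        0.612,
    "solved",              -2.954,     4.578,        -2.63,     1.007,        6.9,   0.008,    0.186,        0.152,
    "cards_moved_avg",     1.111,      0.262,        -0.119,    0.054,        4.9,   0.03,     0.061,        0.093,
    "cards_moved_sd",      0.135,      0.705,        -0.38,     0.147,        6.7,   0.009,    0.072,        0.152
  ) |>
    dplyr::left_join(biomarker_registry()[, c("biomarker", "category", "link")],
                     by = "biomarker") |>
    dplyr::relocate("category", "link", .after = "biomarker")
}

#' Cohort covariate reference distributions
#'
#' The demographic structure of the study cohort (23 participants per
#' group): group-wise age means and SDs and the frequency tables for tablet
#' and Klondike Solitaire proficiency, on the ordinal scale never = 0,
#' yearly-or-less = 1, monthly = 2, weekly = 3, daily = 4. Both generators
#' draw covariates from these distributions.
#'
#' @return A list with `age` (tibble) and `tablet` / `game` count matrices
#'   (rows = groups, columns = ordinal levels 0..4).
#' @export
cohort_reference <- function() {
  lv <- c("never", "yearly", "monthly", "weekly", "daily")
  tablet <- rbind(healthy = c(7, 2, 0, 2, 12),
                  mci     = c(15, 1, 2, 2, 3))
  game   <- rbind(healthy = c(0, 11, 3, 6, 3),
                  mci     = c(0, 6, 2, 8, 7))
  colnames(tablet) <- colnames(game) <- lv
  list(
    age = tibble::tibble(group = c("healthy", "mci"),
                         mean = c(70, 80), sd = c(5.4, 5.2)),
    tablet = tablet,
    game = game
  )
}

#' The consensus-design schema: 21 player actions and 9 cognitive functions
#'
#' `player_actions()` lists the 21 rated player actions (each phrased as the
#' impaired-performance equivalent); `cognitive_functions()` the 9 cognitive
#' functions they were rated against. Player actions 9, 20 and 21 have no
#' captured biomarker (variable difficulty and longitudinal score variance
#' are unobservable in a single session, and aimless-but-legal moves are not
#' detected), which is why the registry holds 23 biomarkers rather than one
#' or more per action.
#'
#' @return A tibble (`player_actions`) or character vector
#'   (`cognitive_functions`).
#' @export
player_actions <- function() {
  tibble::tibble(
    pa = 1:21,
    description = c(
      "takes a lot of time to think of a move",
      "takes a lot of time to move the card",
      "does not move a suitable card from the talon to the suit stack",
      "does not move a suitable card from the build stack to the suit stack",
      "does not move a suitable card from the talon to the build stack",
      "does not move a suitable card from one build stack to another",
      "does not place an ace immediately on an empty suit stack",
      "does not place a king on an empty build stack",
      "moves cards without benefit",
      "flips a lot through the pile",
      "moves a card onto a card with the same color",
      "moves a card to another card with the wrong number",
      "selects cards with very bad precision",
      "taps the playfield with no apparent target",
      "presses the undo button a lot",
      "requests a lot of hints",
      "takes a very long time to finish games",
      "does not have a high score in the game",
      "does not win a lot of games",
      "has scores that vary greatly between games",
      "has a win ratio that drops rapidly with difficulty"
    ),
    captured = !(1:21 %in% c(9L, 20L, 21L))
  )
}

#' @rdname player_actions
#' @export
cognitive_functions <- function() {
  c("mental_flexibility", "inhibitory_control", "working_memory",
    "selective_attention", "visuospatial_ability", "object_recognition",
    "apraxia", "cognitive_planning", "processing_speed")
}
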