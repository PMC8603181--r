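# The 23 digital biomarkers and their extraction from a replayed game.
#
# Denominators (fixed here, configurable where noted):
#   B = board moves = successful + erroneous (+ neutral when
#       include_neutral = TRUE), P = pile moves (flips and recycles),
#   G = B + P = game moves. The pile-move share uses G, not B, so that it is
#   a true percentage bounded by 100 (in draw-1 play flips routinely
#   outnumber board moves).
# A biomarker whose denominator is zero is NA ("undefined"), never 0: a game
# with no pile flips carries no information about beta errors.

#' Catalog of the 23 digital biomarkers
#'
#' The ordered registry of the 23 biomarkers in six categories (time,
#' performance, error, execution, auxiliary, result), with value kind,
#' units, the model link used downstream (identity for continuous, logit for
#' binary), and the player actions each biomarker operationalizes.
#'
#' @return A 23-row tibble with columns `biomarker`, `category`, `kind`,
#'   `units`, `link`, `related_pa` (list column of player-action numbers).
#' @examples
#' nrow(biomarker_registry())          # 23
#' dplyr::count(biomarker_registry(), category)
#' @export
biomarker_registry <- function() {
  tibble::tibble(
    biomarker = c("think_time_avg", "think_time_sd", "move_time_avg",
                  "move_time_sd", "total_time_avg", "total_time_sd",
                  "final_beta_error", "beta_error_pct", "ace_beta_error_pct",
                  "king_beta_error_pct", "pile_move_pct",
                  "successful_move_pct", "erroneous_move_pct",
                  "accuracy_avg", "accuracy_sd", "taps",
                  "undo_move_pct", "hint_move_pct",
                  "game_time", "score", "solved",
                  "cards_moved_avg", "cards_moved_sd"),
    category = c(rep("time", 6), rep("performance", 5), rep("error", 2),
                 rep("execution", 3), rep("auxiliary", 2), rep("result", 5)),
    kind = c(rep("continuous", 6), "boolean", rep("continuous", 13),
             "boolean", "continuous", "continuous"),
    units = c(rep("ms", 6), "boolean", rep("percent", 4),
              rep("percent", 2), rep("percent", 2), "count",
              rep("percent", 2), "ms", "points", "boolean",
              "cards", "cards"),
    link = c(rep("identity", 6), "logit", rep("identity", 13),
             "logit", "identity", "identity"),
    related_pa = list(1L, 1L, 2L, 2L, c(1L, 2L), c(1L, 2L),
                      3L, 3:6, 7L, 8L, 10L,
                      c(11L, 12L), c(11L, 12L),
                      13L, 13L, 14L,
                      15L, 16L,
                      17L, 18L, 19L, 19L, 19L)
  )
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else if (length(x) == 1) 0 else NA_real_
avg <- function(x) if (length(x)) mean(x) else NA_real_

#' Extract the 23 digital biomarkers from one game
#'
#' Replays the log (or accepts an existing [replay()] result) and computes
#' the biomarker vector. Time statistics are taken over successful board
#' gestures; accuracy statistics over all board-gesture pickups; beta error
#' is the share of pile moves made while a relocation was available; ace and
#' king beta errors count gestures taken while the respective placement was
#' available but not played, over all game moves; undo and hint percentages
#' are bounded by 100 via the denominator `G + undo + hint`. Any biomarker
#' with a zero denominator is `NA` (undefined), not 0.
#'
#' @param log An `event_log`, or a `replay_result`.
#' @param include_neutral Count aborted drags (neutral gestures) in the
#'   board-move denominator (default `FALSE`).
#' @return A one-row tibble: metadata (`participant_id`, `game_index`,
#'   `seed`, `n_gestures`) followed by the 23 biomarker columns in registry
#'   order.
#' @export
extract_biomarkers <- function(log, include_neutral = FALSE) {
  rr <- if (inherits(log, "replay_result")) log else replay(log)
  gs <- rr$gestures
  if (!nrow(gs)) stop("cannot extract biomarkers from a log with no gestures",
                      call. = FALSE)
  cls <- gs$classification
  succ <- gs[cls == "successful_board", ]
  err_n <- sum(cls == "erroneous_board")
  neu_n <- sum(cls == "neutral_board")
  pile <- gs[cls == "pile", ]
  undo_n <- sum(cls == "undo")
  hint_n <- sum(cls == "hint")
  board_n <- nrow(succ) + err_n + if (include_neutral) neu_n else 0L
  pile_n <- nrow(pile)
  game_n <- board_n + pile_n
  aux_den <- game_n + undo_n + hint_n

  board_idx <- cls %in% c("successful_board", "erroneous_board", "neutral_board")
  total_ms <- succ$think_ms + succ$move_ms

  # gestures counted as game moves, for the missed-opportunity denominators
  game_idx <- cls %in% c("successful_board", "erroneous_board", "pile") |
    (include_neutral & cls == "neutral_board")
  gmv <- gs[game_idx, ]
  ace_missed <- sum(gmv$ace_playable_before & !gmv$played_ace)
  king_missed <- sum(gmv$king_playable_before & !gmv$played_king_to_empty)

  final <- rr$final_state
  solved <- is_won(final)

  tibble::tibble(
    participant_id = rr$participant_id,
    game_index = rr$game_index,
    seed = rr$seed,
    n_gestures = nrow(gs),
    think_time_avg = avg(succ$think_ms),
    think_time_sd = sd0(succ$think_ms),
    move_time_avg = avg(succ$move_ms),
    move_time_sd = sd0(succ$move_ms),
    total_time_avg = avg(total_ms),
    total_time_sd = sd0(total_ms),
    final_beta_error = if (solved) FALSE else {
      playable_opportunities(final)$any_board_move
    },
    beta_error_pct = pct(sum(pile$board_move_available_before), pile_n),
    ace_beta_error_pct = pct(ace_missed, game_n),
    king_beta_error_pct = pct(king_missed, game_n),
    pile_move_pct = pct(pile_n, game_n),
    successful_move_pct = pct(nrow(succ), board_n),
    erroneous_move_pct = pct(err_n, board_n),
    accuracy_avg = avg(gs$tap_accuracy[board_idx]),
    accuracy_sd = sd0(gs$tap_accuracy[board_idx]),
    taps = sum(cls == "stray"),
    undo_move_pct = pct(undo_n, aux_den),
    hint_move_pct = pct(hint_n, aux_den),
    game_time = max(gs$t_end),
    score = final$score,
    solved = solved,
    cards_moved_avg = avg(succ$cards_moved),
    cards_moved_sd = sd0(succ$cards_moved)
  )
}

#' Assemble the long-format analysis table for a cohort
#'
#' Joins each game's biomarker vector with the participant's covariates:
#' one row per participant-game, ready for [results_table()] /
#' [fit_biomarker_glmm()].
#'
#' @param logs List of `event_log` objects (or `replay_result`s).
#' @param participants Tibble with `participant_id`, `group` ("healthy" or
#'   "mci"), `age`, `tablet_proficiency`, `game_proficiency` (ordinals 0-4,
#'   never = 0 .. daily = 4).
#' @param include_neutral Passed to [extract_biomarkers()].
#' @return A tibble with one row per log: covariates plus the 23 biomarkers.
#' @export
cohort_table <- function(logs, participants, include_neutral = FALSE) {
  participants <- tibble::as_tibble(participants)
  covar_cols <- c("participant_id", "group", "age", "tablet_proficiency",
                  "game_proficiency")
  stopifnot(all(covar_cols %in% names(participants)))
  if (!length(logs)) {
    head <- participants[0, covar_cols]
    head$mci <- integer()
    head <- dplyr::relocate(head, "mci", .after = "group")
    return(dplyr::bind_cols(head, extract_template()))
  }
  bm <- purrr::map_dfr(logs, extract_biomarkers, include_neutral = include_neutral)
  orphans <- setdiff(bm$participant_id, participants$participant_id)
  if (length(orphans)) {
    stop(sprintf("logs reference unknown participants: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::inner_join(participants[covar_cols], bm, by = "participant_id")
  out$mci <- as.integer(out$group == "mci")
  dplyr::relocate(out, "mci", .after = "group")
}

# zero-row game-level columns (everything extract_biomarkers adds beyond id)
extract_template <- function() {
  cols <- c("game_index", "seed", "n_gestures", biomarker_registry()$biomarker)
  tibble::as_tibble(stats::setNames(
    lapply(cols, function(nm) {
      switch(nm,
             game_index = integer(), seed = integer(), n_gestures = integer(),
             final_beta_error = logical(), solved = logical(),
             numeric())
    }), cols))
}
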