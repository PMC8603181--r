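# Deterministic replay: reconstruct the state sequence of a logged game from
# its seed and classify every gesture against the rules engine.

# Locate a card that a player could pick up: talon top, any face-up build
# card, or a suit-stack top (worried move). Returns NULL when not liftable.
locate_card <- function(state, card) {
  tc <- talon_top(state)
  if (!is.na(tc) && tc == card) {
    return(list(zone = "talon", index = 0L, n_cards = 1L))
  }
  for (i in 1:7) {
    li <- length(state$build[[i]])
    fu <- state$face_up[i]
    if (li == 0L || fu == 0L) next
    p <- match(card, state$build[[i]])
    if (!is.na(p)) {
      if (p < li - fu + 1L) return(NULL)  # face-down: not liftable
      return(list(zone = "build", index = i, n_cards = li - p + 1L))
    }
  }
  s <- suit_index(card)
  if (state$foundation[s] == card_rank(card)) {
    return(list(zone = "suit", index = s, n_cards = 1L))
  }
  NULL
}

#' Replay an event log
#'
#' Reconstructs the full state sequence from `klondike_deal(seed)` and
#' classifies every gesture: a pickup/drop pair whose implied relocation is
#' legal is a `successful_board` move; one violating the rank/color/suit
#' rules is `erroneous_board` (the position is unchanged, as the app rejects
#' illegal drops); a drop back at its origin is `neutral_board`; pile, undo,
#' hint and stray taps map to their own classes. Each gesture carries its
#' think time (end of the previous gesture to this pickup or tap; the first
#' gesture counts from t = 0), move time (pickup to drop, 0 for taps), the
#' number of cards moved, the pickup tap accuracy, and the pre-gesture
#' opportunity report from [playable_opportunities()].
#'
#' @param log An `event_log`.
#' @return A `replay_result`: list with `gestures` (one tibble row per
#'   gesture) and `final_state` (the resulting `klondike_state`).
#' @export
replay <- function(log) {
  validate_event_log(log)
  state <- klondike_deal(log$seed, log$draw_mode)
  geo <- as.matrix(log$card_geometry[order(log$card_geometry$card),
                                     c("cx", "cy", "hx", "hy")])
  ev <- log$events
  n_ev <- nrow(ev)
  recs <- vector("list", n_ev)
  g <- 0L
  prev_end <- 0
  i <- 1L
  while (i <= n_ev) {
    kind <- ev$kind[i]
    opp <- opportunities_list(state)
    if (kind == "pickup") {
      if (i == n_ev || ev$kind[i + 1L] != "drop") {
        stop("replay desync: pickup without a matching drop", call. = FALSE)
      }
      card <- ev$target_card[i]
      loc <- locate_card(state, card)
      if (is.null(loc)) {
        stop(sprintf("replay desync: card %s is not liftable at event %d",
                     card_label(card), i), call. = FALSE)
      }
      acc <- tap_accuracy(c(ev$x[i], ev$y[i]), geo[card, ])
      dz <- ev$target_zone[i + 1L]
      di <- ev$target_index[i + 1L]
      played_ace <- FALSE
      played_king_empty <- FALSE
      if (dz == loc$zone && di == loc$index) {
        cls <- "neutral_board"
      } else {
        mv <- mk_move("relocation", loc$zone, loc$index, dz, di, loc$n_cards)
        ok <- check_relocation(state, mv)
        if (isTRUE(ok)) {
          dest_empty <- dz == "build" && length(state$build[[di]]) == 0L
          state <- apply_relocation(state, mv)
          cls <- "successful_board"
          played_ace <- dz == "suit" && card_rank(card) == 1L
          played_king_empty <- dest_empty && card_rank(card) == 13L
        } else {
          cls <- "erroneous_board"
        }
      }
      g <- g + 1L
      recs[[g]] <- list(
        gesture = g, classification = cls,
        think_ms = ev$t[i] - prev_end, move_ms = ev$t[i + 1L] - ev$t[i],
        cards_moved = loc$n_cards, tap_accuracy = acc,
        board_move_available_before = opp[["any_board_move"]],
        ace_playable_before = opp[["ace_playable"]],
        king_playable_before = opp[["king_playable_to_empty"]],
        played_ace = played_ace, played_king_to_empty = played_king_empty,
        t_start = ev$t[i], t_end = ev$t[i + 1L])
      prev_end <- ev$t[i + 1L]
      i <- i + 2L
    } else {
      cls <- switch(kind, pile_tap = "pile", undo_tap = "undo",
                    hint_tap = "hint", stray_tap = "stray",
                    stop("replay desync: unexpected drop", call. = FALSE))
      if (kind == "pile_tap" && (length(state$stock) || length(state$talon))) {
        state <- apply_pile_flip(state)
      } else if (kind == "undo_tap" && length(state$history)) {
        state <- apply_undo(state)
      }
      g <- g + 1L
      recs[[g]] <- list(
        gesture = g, classification = cls,
        think_ms = ev$t[i] - prev_end, move_ms = 0,
        cards_moved = NA_integer_, tap_accuracy = NA_real_,
        board_move_available_before = opp[["any_board_move"]],
        ace_playable_before = opp[["ace_playable"]],
        king_playable_before = opp[["king_playable_to_empty"]],
        played_ace = FALSE, played_king_to_empty = FALSE,
        t_start = ev$t[i], t_end = ev$t[i])
      prev_end <- ev$t[i]
      i <- i + 1L
    }
  }
  gestures <- if (g) {
    dplyr::bind_rows(lapply(recs[seq_len(g)], tibble::as_tibble))
  } else {
    tibble::tibble(gesture = integer(), classification = character(),
                   think_ms = numeric(), move_ms = numeric(),
                   cards_moved = integer(), tap_accuracy = numeric(),
                   board_move_available_before = logical(),
                   ace_playable_before = logical(),
                   king_playable_before = logical(),
                   played_ace = logical(), played_king_to_empty = logical(),
                   t_start = numeric(), t_end = numeric())
  }
  structure(list(gestures = gestures, final_state = state,
                 participant_id = log$participant_id,
                 game_index = log$game_index, seed = log$seed),
            class = "replay_result")
}

#' @export
print.replay_result <- function(x, ...) {
  cat(sprintf("<replay_result> %s game %d: %d gestures, score %d%s\n",
              x$participant_id, x$game_index, nrow(x$gestures),
              x$final_state$score,
              if (is_won(x$final_state)) ", solved" else ""))
  invisible(x)
}
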