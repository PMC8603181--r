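# Independent oracles and state constructors shared across the test files.

# Build a klondike_state directly from zone contents (bypassing deal()), so
# hand-crafted positions can be tested. Validates before returning.
make_state <- function(build, face_up, foundation = rep(0L, 4L),
                       stock = integer(0), talon = integer(0),
                       draw_mode = "draw1", score = 0L) {
  st <- structure(
    list(build = lapply(build, as.integer), face_up = as.integer(face_up),
         foundation = as.integer(foundation), stock = as.integer(stock),
         talon = as.integer(talon), score = as.integer(score),
         move_count = 0L, draw_mode = draw_mode, seed = 0L,
         shuffle_scheme = "manual", history = list()),
    class = "klondike_state")
  validate_state(st)
  st
}

# Positional state equality, ignoring history.
state_equal <- function(a, b) {
  identical(a$build, b$build) && identical(a$face_up, b$face_up) &&
    identical(a$foundation, b$foundation) && identical(a$stock, b$stock) &&
    identical(a$talon, b$talon) && a$score == b$score &&
    a$move_count == b$move_count
}

# Brute-force legality oracle: enumerates every (movable run head,
# destination) pair and rechecks legality from the card arithmetic alone.
# Independent of relocations_list(): iterates destinations first and derives
# acceptable cards, instead of iterating sources.
oracle_relocations <- function(state) {
  rank_of <- function(id) (id - 1) %% 13 + 1
  suit_of <- function(id) (id - 1) %/% 13 + 1
  is_red <- function(id) suit_of(id) %in% c(2, 3)
  # movable heads: (card, zone, index, n_cards)
  heads <- list()
  if (length(state$talon)) {
    heads[[length(heads) + 1L]] <-
      list(card = state$talon[length(state$talon)], zone = "talon",
           index = 0L, n = 1L, top_only = TRUE)
  }
  for (i in 1:7) {
    li <- length(state$build[[i]])
    fu <- state$face_up[i]
    if (li == 0 || fu == 0) next
    for (p in (li - fu + 1):li) {
      heads[[length(heads) + 1L]] <-
        list(card = state$build[[i]][p], zone = "build", index = i,
             n = li - p + 1L, top_only = p == li)
    }
  }
  for (s in 1:4) {
    if (state$foundation[s] > 0) {
      heads[[length(heads) + 1L]] <-
        list(card = (s - 1) * 13 + state$foundation[s], zone = "suit",
             index = s, n = 1L, top_only = TRUE)
    }
  }
  out <- character(0)
  for (h in heads) {
    for (j in 1:7) {
      if (h$zone == "build" && h$index == j) next
      dst <- state$build[[j]]
      ok <- if (!length(dst)) {
        rank_of(h$card) == 13
      } else {
        top <- dst[length(dst)]
        rank_of(h$card) == rank_of(top) - 1 && is_red(h$card) != is_red(top)
      }
      if (ok) {
        out <- c(out, paste("relocation", h$zone, h$index, "build", j, h$n))
      }
    }
    if (h$top_only && h$zone != "suit") {
      s <- suit_of(h$card)
      if (state$foundation[s] == rank_of(h$card) - 1) {
        out <- c(out, paste("relocation", h$zone, h$index, "suit", s, 1))
      }
    }
  }
  sort(out)
}

move_signature <- function(moves) {
  reloc <- moves[moves$kind == "relocation", , drop = FALSE]
  if (!nrow(reloc)) return(character(0))
  sort(paste("relocation", reloc$from_zone, reloc$from_index,
             reloc$to_zone, reloc$to_index, reloc$n_cards))
}

# Random mid-game state: walk k random legal moves from a random deal.
random_mid_state <- function(seed, k = 25) {
  state <- klondike_deal(seed)
  for (step in seq_len(k)) {
    moves <- solitairebm:::legal_moves_list(state)
    if (!length(moves)) break
    state <- apply_move(state, moves[[sample.int(length(moves), 1)]])
  }
  state
}

# Translate an engine move into pickup/drop events (for hand-built logs).
move_to_events <- function(state, move, t_pickup, t_drop,
                           geometry = default_card_geometry()) {
  head_card <- switch(move$from_zone,
    talon = state$talon[length(state$talon)],
    build = {
      li <- length(state$build[[move$from_index]])
      state$build[[move$from_index]][li - move$n_cards + 1L]
    },
    suit = (move$from_index - 1L) * 13L + state$foundation[move$from_index])
  g <- geometry[geometry$card == head_card, ]
  tibble::tibble(
    t = c(t_pickup, t_drop), kind = c("pickup", "drop"),
    x = c(g$cx, 0.5), y = c(g$cy, 0.5),
    target_card = c(head_card, NA_integer_),
    target_zone = c(NA_character_, move$to_zone),
    target_index = c(NA_integer_, move$to_index))
}

# A perfect (error-free, non-overlooking) agent profile.
perfect_profile <- function(persistence = 3L) {
  cognitive_profile(p_overlook = 0, p_error = 0, p_undo = 0, p_hint = 0,
                    stray_rate = 0, persistence = persistence)
}

# ICC oracle: mean squares from aov() (independent QR-based fit), plugged
# into the consistency formulas.
icc_aov_oracle <- function(m, unit = "average") {
  d <- expand.grid(rater = factor(seq_len(nrow(m))),
                   target = factor(seq_len(ncol(m))))
  d$y <- as.vector(m[cbind(as.integer(d$rater), as.integer(d$target))])
  tab <- summary(stats::aov(y ~ target + rater, data = d))[[1]]
  ms_r <- tab["target", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  k <- nrow(m)
  if (unit == "average") (ms_r - ms_e) / ms_r
  else (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}
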