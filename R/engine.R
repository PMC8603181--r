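# Klondike Solitaire rules engine.
#
# A position (`klondike_state`) is a plain list; all mutation goes through
# apply_move() so that every change is recorded on an undo history and the
# 52-card conservation invariant can never be broken by construction.

#' Deal a Klondike Solitaire game
#'
#' Deals a standard 52-card deck: build stacks 1..7 receive 1..7 cards (top
#' card face-up), the remaining 24 cards form the face-down stock. The deck
#' permutation is a pure function of `seed` (shuffle scheme
#' `"mt-sample-v1"`: Mersenne-Twister + rejection sampling, isolated from the
#' caller's RNG state), so a deal can be replayed exactly from its seed.
#'
#' @param seed Integer game seed; identical seeds give bit-identical deals.
#' @param draw_mode `"draw1"` (default) or `"draw3"`: how many cards a pile
#'   tap moves from the stock to the talon.
#' @return A `klondike_state` object with zones `build` (7 stacks, bottom
#'   first), `face_up` (face-up counts per stack), `foundation` (top rank per
#'   suit, 0 = empty), `stock`, `talon`, plus `score`, `move_count` and the
#'   undo `history`.
#' @examples
#' st <- klondike_deal(1)
#' sum(lengths(st$build))   # 28 cards on the board
#' length(st$stock)         # 24 in the stock
#' @export
klondike_deal <- function(seed, draw_mode = c("draw1", "draw3")) {
  draw_mode <- match.arg(draw_mode)
  perm <- with_rng(seed, sample.int(52L))
  build <- vector("list", 7L)
  k <- 0L
  for (i in 1:7) {
    build[[i]] <- perm[(k + 1L):(k + i)]
    k <- k + i
  }
  st <- structure(
    list(
      build = build,
      face_up = rep(1L, 7L),
      foundation = rep(0L, 4L),
      stock = perm[(k + 1L):52L],
      talon = integer(0),
      score = 0L,
      move_count = 0L,
      draw_mode = draw_mode,
      seed = as.integer(seed %% .Machine$integer.max),
      shuffle_scheme = "mt-sample-v1",
      history = list()
    ),
    class = "klondike_state"
  )
  st
}

# number of cards drawn per pile tap
draw_count <- function(state) if (identical(state$draw_mode, "draw3")) 3L else 1L

# top card of a zone, or NA
build_top <- function(state, i) {
  s <- state$build[[i]]
  if (length(s)) s[length(s)] else NA_integer_
}
talon_top <- function(state) {
  if (length(state$talon)) state$talon[length(state$talon)] else NA_integer_
}

# Can `card` head a run placed on build stack j?
can_place_on_build <- function(state, card, j) {
  top <- build_top(state, j)
  if (is.na(top)) return(card_rank(card) == 13L)
  card_rank(card) == card_rank(top) - 1L && opposite_color(card, top)
}

can_place_on_suit <- function(state, card) {
  state$foundation[suit_index(card)] == card_rank(card) - 1L
}

mk_move <- function(kind, from_zone = NA_character_, from_index = NA_integer_,
                    to_zone = NA_character_, to_index = NA_integer_,
                    n_cards = NA_integer_) {
  list(kind = kind, from_zone = from_zone, from_index = as.integer(from_index),
       to_zone = to_zone, to_index = as.integer(to_index),
       n_cards = as.integer(n_cards))
}

# All legal relocations as a list of move lists (hot path: no tibbles here).
relocations_list <- function(state) {
  out <- vector("list", 32L)
  n <- 0L
  push <- function(m) {
    n <<- n + 1L
    out[[n]] <<- m
  }
  # talon top
  tc <- talon_top(state)
  if (!is.na(tc)) {
    if (can_place_on_suit(state, tc)) {
      push(mk_move("relocation", "talon", 0L, "suit", suit_index(tc), 1L))
    }
    for (j in 1:7) {
      if (can_place_on_build(state, tc, j)) {
        push(mk_move("relocation", "talon", 0L, "build", j, 1L))
      }
    }
  }
  # build stacks: any face-up card heads a movable run
  for (i in 1:7) {
    li <- length(state$build[[i]])
    fu <- state$face_up[i]
    if (li == 0L || fu == 0L) next
    for (p in (li - fu + 1L):li) {
      head_card <- state$build[[i]][p]
      nc <- li - p + 1L
      for (j in 1:7) {
        if (j == i) next
        if (can_place_on_build(state, head_card, j)) {
          push(mk_move("relocation", "build", i, "build", j, nc))
        }
      }
      if (p == li && can_place_on_suit(state, head_card)) {
        push(mk_move("relocation", "build", i, "suit", suit_index(head_card), 1L))
      }
    }
  }
  # worried moves: foundation top back onto a build stack
  for (s in 1:4) {
    r <- state$foundation[s]
    if (r == 0L) next
    wc <- card_id(r, s)
    for (j in 1:7) {
      if (can_place_on_build(state, wc, j)) {
        push(mk_move("relocation", "suit", s, "build", j, 1L))
      }
    }
  }
  if (n == 0L) list() else out[seq_len(n)]
}

legal_moves_list <- function(state) {
  moves <- relocations_list(state)
  if (length(state$stock) || length(state$talon)) {
    moves[[length(moves) + 1L]] <- mk_move("pile_flip")
  }
  moves
}

#' Enumerate legal moves
#'
#' Lists every legal move in a position: relocations among talon, build
#' stacks and suit stacks (including "worried" moves from a suit stack back
#' onto a build stack), plus a `pile_flip` whenever the stock or talon is
#' nonempty. A build destination accepts a card one rank below its top card
#' and of the opposite color; an empty build stack accepts only a
#' king-headed run; a suit stack accepts only the next rank of its suit.
#'
#' @param state A `klondike_state`.
#' @param validate Check state invariants first (default `TRUE`).
#' @return A tibble with one row per move: `kind`, `from_zone`, `from_index`,
#'   `to_zone`, `to_index`, `n_cards`.
#' @export
legal_moves <- function(state, validate = TRUE) {
  if (validate) validate_state(state)
  moves <- legal_moves_list(state)
  if (!length(moves)) {
    return(tibble::tibble(kind = character(), from_zone = character(),
                          from_index = integer(), to_zone = character(),
                          to_index = integer(), n_cards = integer()))
  }
  dplyr::bind_rows(lapply(moves, tibble::as_tibble))
}

#' Validate a Klondike position
#'
#' Checks the state invariants: the five zones together hold exactly one
#' 52-card deck, face-up counts are consistent, every face-up run on a build
#' stack strictly descends with alternating colors, and foundations hold
#' ranks 0..13. Errors with the violated rule; invisibly returns the state.
#'
#' @param state A `klondike_state`.
#' @export
validate_state <- function(state) {
  if (!inherits(state, "klondike_state")) {
    stop("not a klondike_state", call. = FALSE)
  }
  founds <- unlist(lapply(1:4, function(s) {
    r <- state$foundation[s]
    if (r < 0L || r > 13L) stop("state invariant violated: foundation rank outside 0..13",
                                call. = FALSE)
    if (r == 0L) integer(0) else card_id(1:r, s)
  }))
  all_cards <- c(unlist(state$build), founds, state$stock, state$talon)
  if (length(all_cards) != 52L || !setequal(all_cards, 1:52) ||
      anyDuplicated(all_cards)) {
    stop("state invariant violated: zones do not partition the 52-card deck",
         call. = FALSE)
  }
  for (i in 1:7) {
    li <- length(state$build[[i]])
    fu <- state$face_up[i]
    if (fu < 0L || fu > li) {
      stop("state invariant violated: face-up count out of range", call. = FALSE)
    }
    if (li > 0L && fu == 0L) {
      stop("state invariant violated: nonempty build stack with no face-up card",
           call. = FALSE)
    }
    if (fu >= 2L) {
      run <- state$build[[i]][(li - fu + 1L):li]
      ranks <- card_rank(run)
      if (any(diff(ranks) != -1L) ||
          any(!opposite_color(run[-fu], run[-1L]))) {
        stop("state invariant violated: face-up run not descending with alternating colors",
             call. = FALSE)
      }
    }
  }
  invisible(state)
}

#' Has the game been won?
#'
#' @param state A `klondike_state`.
#' @return `TRUE` iff all four suit stacks hold 13 cards.
#' @export
is_won <- function(state) all(state$foundation == 13L)

# scoring scheme: classic defaults, pluggable via options (see vignette)
score_delta <- function(from_zone, to_zone, flipped) {
  delta <- 0L
  if (to_zone == "suit") delta <- delta + 10L
  if (from_zone == "talon" && to_zone == "build") delta <- delta + 5L
  if (from_zone == "suit") delta <- delta - 15L
  if (flipped) delta <- delta + 5L
  delta
}

# is `move` (a move list) legal in `state`? returns TRUE or an error message
check_relocation <- function(state, move) {
  fz <- move$from_zone; tz <- move$to_zone
  n <- move$n_cards
  if (fz == "talon") {
    card <- talon_top(state)
    if (is.na(card)) return("talon is empty")
    if (n != 1L) return("only one card can leave the talon")
  } else if (fz == "build") {
    i <- move$from_index
    li <- length(state$build[[i]])
    if (n < 1L || n > state$face_up[i]) {
      return("run exceeds the face-up cards of the source stack")
    }
    card <- state$build[[i]][li - n + 1L]
  } else if (fz == "suit") {
    s <- move$from_index
    if (state$foundation[s] == 0L) return("suit stack is empty")
    if (n != 1L) return("only one card can leave a suit stack")
    card <- card_id(state$foundation[s], s)
  } else {
    return("unknown source zone")
  }
  if (tz == "suit") {
    if (n != 1L) return("only single cards go to a suit stack")
    if (!can_place_on_suit(state, card)) {
      return("suit stack accepts only the next rank of its suit")
    }
    if (move$to_index != suit_index(card)) return("wrong suit stack")
  } else if (tz == "build") {
    j <- move$to_index
    if (fz == "build" && j == move$from_index) return("source equals destination")
    top <- build_top(state, j)
    if (is.na(top)) {
      if (card_rank(card) != 13L) return("an empty build stack accepts only a king")
    } else {
      if (card_rank(card) != card_rank(top) - 1L) {
        return("destination rank must be exactly one higher")
      }
      if (!opposite_color(card, top)) return("destination color must be opposite")
    }
  } else {
    return("unknown destination zone")
  }
  TRUE
}

apply_relocation <- function(state, move) {
  ok <- check_relocation(state, move)
  if (!isTRUE(ok)) {
    stop(sprintf("illegal move: %s", ok), call. = FALSE)
  }
  fz <- move$from_zone; tz <- move$to_zone
  n <- move$n_cards
  prev_score <- state$score
  flipped <- FALSE
  # remove from source
  if (fz == "talon") {
    cards <- talon_top(state)
    state$talon <- state$talon[-length(state$talon)]
  } else if (fz == "build") {
    i <- move$from_index
    li <- length(state$build[[i]])
    cards <- state$build[[i]][(li - n + 1L):li]
    state$build[[i]] <- state$build[[i]][seq_len(li - n)]
    state$face_up[i] <- state$face_up[i] - n
    if (length(state$build[[i]]) && state$face_up[i] == 0L) {
      state$face_up[i] <- 1L
      flipped <- TRUE
    }
  } else { # suit
    s <- move$from_index
    cards <- card_id(state$foundation[s], s)
    state$foundation[s] <- state$foundation[s] - 1L
  }
  # place on destination
  if (tz == "suit") {
    state$foundation[move$to_index] <- state$foundation[move$to_index] + 1L
  } else {
    j <- move$to_index
    state$build[[j]] <- c(state$build[[j]], cards)
    state$face_up[j] <- state$face_up[j] + n
  }
  state$score <- max(0L, state$score + score_delta(fz, tz, flipped))
  state$move_count <- state$move_count + 1L
  state$history[[length(state$history) + 1L]] <-
    list(type = "relocation", move = move, flipped = flipped,
         prev_score = prev_score)
  state
}

apply_pile_flip <- function(state) {
  if (!length(state$stock) && !length(state$talon)) {
    stop("illegal move: stock and talon are both empty", call. = FALSE)
  }
  prev_score <- state$score
  if (length(state$stock)) {
    k <- min(draw_count(state), length(state$stock))
    state$talon <- c(state$talon, state$stock[seq_len(k)])
    state$stock <- state$stock[-seq_len(k)]
    rec <- list(type = "pile_flip", recycled = FALSE, n_drawn = k,
                prev_score = prev_score)
  } else {
    state$stock <- state$talon
    state$talon <- integer(0)
    rec <- list(type = "pile_flip", recycled = TRUE, n_drawn = 0L,
                prev_score = prev_score)
  }
  state$move_count <- state$move_count + 1L
  state$history[[length(state$history) + 1L]] <- rec
  state
}

apply_undo <- function(state) {
  h <- length(state$history)
  if (h == 0L) stop("undo requires a nonempty history", call. = FALSE)
  rec <- state$history[[h]]
  state$history <- state$history[-h]
  if (rec$type == "pile_flip") {
    if (rec$recycled) {
      state$talon <- state$stock
      state$stock <- integer(0)
    } else {
      k <- rec$n_drawn
      nt <- length(state$talon)
      state$stock <- c(state$talon[(nt - k + 1L):nt], state$stock)
      state$talon <- state$talon[seq_len(nt - k)]
    }
  } else {
    mv <- rec$move
    n <- mv$n_cards
    # take the cards back off the destination
    if (mv$to_zone == "suit") {
      s <- mv$to_index
      cards <- card_id(state$foundation[s], s)
      state$foundation[s] <- state$foundation[s] - 1L
    } else {
      j <- mv$to_index
      lj <- length(state$build[[j]])
      cards <- state$build[[j]][(lj - n + 1L):lj]
      state$build[[j]] <- state$build[[j]][seq_len(lj - n)]
      state$face_up[j] <- state$face_up[j] - n
    }
    # restore the source
    if (mv$from_zone == "talon") {
      state$talon <- c(state$talon, cards)
    } else if (mv$from_zone == "suit") {
      state$foundation[mv$from_index] <- state$foundation[mv$from_index] + 1L
    } else {
      i <- mv$from_index
      if (rec$flipped) state$face_up[i] <- 0L
      state$build[[i]] <- c(state$build[[i]], cards)
      state$face_up[i] <- state$face_up[i] + n
    }
  }
  state$score <- rec$prev_score
  state$move_count <- state$move_count - 1L
  state
}

#' Apply a move to a position
#'
#' Applies a relocation, pile flip, undo or hint and returns the successor
#' state. Relocations auto-flip a newly exposed build-stack card (face-up)
#' and update the score: +5 talon to build, +10 anything to a suit stack, +5
#' for turning a face-down card, -15 for a worried move off a suit stack,
#' floored at 0. A pile flip draws `draw_mode` cards from the stock, or
#' recycles the talon into the stock when the stock is empty. Undo restores
#' the previous state exactly, score included. A hint is recorded by the
#' telemetry layer only and leaves the state untouched.
#'
#' @param state A `klondike_state`.
#' @param move A move as returned by [legal_moves()] (one-row data frame or
#'   named list with `kind` and, for relocations, `from_zone`, `from_index`,
#'   `to_zone`, `to_index`, `n_cards`).
#' @return The successor `klondike_state`.
#' @export
apply_move <- function(state, move) {
  if (is.data.frame(move)) {
    stopifnot(nrow(move) == 1L)
    move <- as.list(move)
  }
  switch(move$kind,
    relocation = apply_relocation(state, move),
    pile_flip  = apply_pile_flip(state),
    undo       = apply_undo(state),
    hint       = state,
    stop(sprintf("unknown move kind '%s'", move$kind), call. = FALSE)
  )
}

# Fast internal opportunity report (logical triple).
opportunities_list <- function(state) {
  tc <- talon_top(state)
  ace <- (!is.na(tc) && card_rank(tc) == 1L)
  if (!ace) {
    for (i in 1:7) {
      tp <- build_top(state, i)
      if (!is.na(tp) && card_rank(tp) == 1L) { ace <- TRUE; break }
    }
  }
  king <- FALSE
  if (any(lengths(state$build) == 0L)) {
    if (!is.na(tc) && card_rank(tc) == 13L) king <- TRUE
    if (!king) {
      for (i in 1:7) {
        li <- length(state$build[[i]])
        fu <- state$face_up[i]
        if (li == 0L) next
        p <- li - fu + 1L
        # a king heading the face-up run, with cards still buried beneath it
        if (card_rank(state$build[[i]][p]) == 13L && p > 1L) { king <- TRUE; break }
      }
    }
  }
  any_board <- length(relocations_list(state)) > 0L
  c(ace_playable = ace, king_playable_to_empty = king, any_board_move = any_board)
}

#' Playable opportunities in a position
#'
#' Reports whether productive placements are currently available:
#' `ace_playable` (a face-up ace can go to a suit stack now),
#' `king_playable_to_empty` (an empty build stack exists and a movable
#' king-headed run could fill it -- whole-stack king runs that would merely
#' shuttle between empty columns are excluded), and `any_board_move` (any
#' legal relocation exists, i.e. [legal_moves()] minus pile flips is
#' nonempty). These pre-gesture booleans feed the missed-opportunity (beta
#' error) biomarkers.
#'
#' @param state A `klondike_state`.
#' @return A one-row tibble with the three logical columns.
#' @export
playable_opportunities <- function(state) {
  v <- opportunities_list(state)
  tibble::tibble(ace_playable = v[["ace_playable"]],
                 king_playable_to_empty = v[["king_playable_to_empty"]],
                 any_board_move = v[["any_board_move"]])
}

#' @export
print.klondike_state <- function(x, ...) {
  lab <- function(v) if (length(v)) paste(card_label(v), collapse = " ") else "-"
  cat(sprintf("Klondike deal (seed %d, %s)  score %d  moves %d%s\n",
              x$seed, x$draw_mode, x$score, x$move_count,
              if (is_won(x)) "  WON" else ""))
  cat(sprintf("stock: %d cards   talon top: %s\n", length(x$stock),
              if (length(x$talon)) card_label(talon_top(x)) else "-"))
  f <- ifelse(x$foundation == 0L, "-",
              paste0(RANK_LABELS[pmax(x$foundation, 1L)],
                     c("C", "D", "H", "S")))
  cat("foundations:", paste(f, collapse = " "), "\n")
  for (i in 1:7) {
    s <- x$build[[i]]
    li <- length(s)
    fu <- x$face_up[i]
    shown <- if (li == 0L) "-" else paste(
      c(rep("##", li - fu), if (fu > 0L) card_label(s[(li - fu + 1L):li])),
      collapse = " ")
    cat(sprintf("  stack %d: %s\n", i, shown))
  }
  invisible(x)
}
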