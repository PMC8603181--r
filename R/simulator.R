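# Agent-based synthetic players.
#
# A parameterized player (cognitive profile) plays the engine with a greedy
# priority policy; impairment is expressed as slower lognormal timing, a
# higher chance of overlooking available relocations, more illegal drop
# attempts, noisier tap placement, more stray taps and less persistence
# before quitting. The agent emulates study participants, not optimal play:
# there is no look-ahead search.

#' Cognitive profile of a synthetic player
#'
#' @param think_mu,think_sigma Lognormal meanlog/sdlog of per-gesture think
#'   time in ms (median think time is `exp(think_mu)`).
#' @param move_mu,move_sigma Lognormal parameters of drag (move) time in ms.
#' @param p_overlook Probability of not perceiving any single available
#'   relocation at a decision point.
#' @param p_error Probability per decision of attempting an illegal drop.
#' @param tap_sd Gaussian jitter (normalized screen units) of pickup taps
#'   around the card center.
#' @param p_undo,p_hint Per-decision probabilities of pressing undo /
#'   requesting a hint.
#' @param stray_rate Expected stray taps per minute of play.
#' @param persistence Number of consecutive fruitless passes through the
#'   pile before the player quits (>= 1).
#' @return A `cognitive_profile` object.
#' @export
cognitive_profile <- function(think_mu = log(2000), think_sigma = 0.5,
                              move_mu = log(700), move_sigma = 0.4,
                              p_overlook = 0.1, p_error = 0.03,
                              tap_sd = 0.01, p_undo = 0.01, p_hint = 0.01,
                              stray_rate = 0.5, persistence = 3L) {
  stopifnot(think_sigma > 0, move_sigma > 0,
            p_overlook >= 0, p_overlook <= 1, p_error >= 0, p_error <= 1,
            p_undo >= 0, p_undo <= 1, p_hint >= 0, p_hint <= 1,
            tap_sd >= 0, stray_rate >= 0, persistence >= 1)
  structure(list(think_mu = think_mu, think_sigma = think_sigma,
                 move_mu = move_mu, move_sigma = move_sigma,
                 p_overlook = p_overlook, p_error = p_error,
                 tap_sd = tap_sd, p_undo = p_undo, p_hint = p_hint,
                 stray_rate = stray_rate, persistence = as.integer(persistence)),
            class = "cognitive_profile")
}

#' Group default profiles
#'
#' Defaults emulating the two study groups: the healthy profile thinks
#' faster (median 1.8 s vs 3.2 s), overlooks fewer available moves, makes
#' fewer illegal attempts, taps closer to card centers, fidget-taps less and
#' persists longer before quitting. Effect directions follow the rated
#' player actions; magnitudes are package defaults (see the methods
#' vignette), not estimates from data.
#'
#' @export
healthy_profile <- function() {
  cognitive_profile(think_mu = log(1800), think_sigma = 0.45,
                    move_mu = log(650), move_sigma = 0.35,
                    p_overlook = 0.06, p_error = 0.02, tap_sd = 0.008,
                    p_undo = 0.01, p_hint = 0.01, stray_rate = 0.2,
                    persistence = 3L)
}

#' @rdname healthy_profile
#' @export
mci_profile <- function() {
  cognitive_profile(think_mu = log(3200), think_sigma = 0.55,
                    move_mu = log(800), move_sigma = 0.45,
                    p_overlook = 0.22, p_error = 0.08, tap_sd = 0.016,
                    p_undo = 0.015, p_hint = 0.015, stray_rate = 1.0,
                    persistence = 2L)
}

# Candidate productive relocations in greedy priority order:
#   1. aces and twos onto the suit stacks (always safe),
#   2. full face-up run onto another stack when it turns a face-down card,
#   3. talon to a build stack,
#   4. whole-stack run relocation that vacates a column while a king waits,
#   5. other suit-stack placements last: delaying them keeps tableau runs
#      growing (the standard keep-your-options-open strategy), so deep games
#      relocate progressively longer runs.
policy_moves <- function(state) {
  cand <- list()
  moves <- relocations_list(state)
  if (!length(moves)) return(cand)
  to_suit <- list(); reveals <- list(); talon_build <- list(); vacate <- list()
  king_waiting <- {
    tc <- talon_top(state)
    w <- !is.na(tc) && card_rank(tc) == 13L
    if (!w) {
      for (i in 1:7) {
        li <- length(state$build[[i]])
        if (li == 0L) next
        p <- li - state$face_up[i] + 1L
        if (p > 1L && card_rank(state$build[[i]][p]) == 13L) { w <- TRUE; break }
      }
    }
    w
  }
  suit_late <- list()
  for (m in moves) {
    if (m$to_zone == "suit" && m$from_zone != "suit") {
      r <- if (m$from_zone == "talon") card_rank(talon_top(state)) else {
        card_rank(build_top(state, m$from_index))
      }
      if (r <= 2L) to_suit <- c(to_suit, list(m)) else {
        suit_late <- c(suit_late, list(m))
      }
    } else if (m$from_zone == "build" && m$to_zone == "build") {
      li <- length(state$build[[m$from_index]])
      p <- li - m$n_cards + 1L
      full_run <- m$n_cards == state$face_up[m$from_index]
      if (full_run && p > 1L) {
        reveals <- c(reveals, list(m))
      } else if (full_run && p == 1L && king_waiting &&
                 length(state$build[[m$to_index]]) > 0L) {
        vacate <- c(vacate, list(m))
      }
    } else if (m$from_zone == "talon" && m$to_zone == "build") {
      talon_build <- c(talon_build, list(m))
    }
    # worried (suit -> build) moves are never chosen by the policy
  }
  c(to_suit, reveals, talon_build, vacate, suit_late)
}

# an illegal relocation attempt for error injection, or NULL if none exists
pick_illegal_move <- function(state) {
  heads <- list()
  tc <- talon_top(state)
  if (!is.na(tc)) heads <- c(heads, list(list(zone = "talon", index = 0L,
                                              card = tc, n = 1L)))
  for (i in 1:7) {
    tp <- build_top(state, i)
    if (!is.na(tp)) heads <- c(heads, list(list(zone = "build", index = i,
                                                card = tp, n = 1L)))
  }
  if (!length(heads)) return(NULL)
  h <- heads[[sample.int(length(heads), 1L)]]
  bad <- Filter(function(j) {
    !(h$zone == "build" && h$index == j) && !can_place_on_build(state, h$card, j)
  }, 1:7)
  if (!length(bad)) return(NULL)
  j <- bad[[sample.int(length(bad), 1L)]]
  list(card = h$card, from = h, to_zone = "build", to_index = j)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate one game by a synthetic player
#'
#' Plays `klondike_deal(seed)` with the greedy policy of the profile: at
#' each decision point every available productive relocation is
#' independently overlooked with probability `p_overlook`; if none survives,
#' the player flips the pile. Illegal drop attempts, undos, hint requests
#' and stray taps are injected per the profile, timing is sampled from the
#' lognormal components, and the player quits after `persistence` fruitless
#' full passes through the pile. The result is fully reproducible from
#' `(profile, seed, rng_seed)`.
#'
#' @param profile A [cognitive_profile()].
#' @param seed Game seed for the deal.
#' @param rng_seed Seed for the behavioral randomness.
#' @param participant_id,game_index Metadata stamped into the log header.
#' @param draw_mode `"draw1"` or `"draw3"`.
#' @param max_gestures Safety cap on log length.
#' @return An `event_log`.
#' @export
simulate_game <- function(profile, seed, rng_seed,
                          participant_id = "sim", game_index = 1L,
                          draw_mode = "draw1", max_gestures = 3000L) {
  stopifnot(inherits(profile, "cognitive_profile"))
  geo <- default_card_geometry()
  geo_m <- as.matrix(geo[order(geo$card), c("cx", "cy", "hx", "hy")])
  with_rng(rng_seed, {
    state <- klondike_deal(seed, draw_mode)
    t_now <- 0
    ev <- list(); ne <- 0L
    add <- function(t, kind, x, y, card = NA_integer_,
                    zone = NA_character_, index = NA_integer_) {
      ne <<- ne + 1L
      ev[[ne]] <<- list(t = t, kind = kind, x = x, y = y,
                        target_card = card, target_zone = zone,
                        target_index = index)
    }
    think_time <- function(scale = 1) scale * stats::rlnorm(1, profile$think_mu,
                                                            profile$think_sigma)
    emit_strays <- function(duration_ms) {
      k <- stats::rpois(1, profile$stray_rate * duration_ms / 60000)
      if (k > 0L) {
        for (tt in sort(stats::runif(k, t_now, t_now + duration_ms))) {
          add(tt, "stray_tap", stats::runif(1), stats::runif(1))
        }
      }
    }
    tap <- function(kind, x, y, scale = 0.5) {
      th <- think_time(scale)
      emit_strays(th)
      t_now <<- t_now + th
      add(t_now, kind, x, y)
    }
    pickup_drop <- function(card, from, to_zone, to_index) {
      th <- think_time()
      emit_strays(th)
      mv <- stats::rlnorm(1, profile$move_mu, profile$move_sigma)
      pos <- clamp01(geo_m[card, 1:2] + stats::rnorm(2, 0, profile$tap_sd))
      add(t_now + th, "pickup", pos[1], pos[2], card = card)
      drop_pos <- clamp01(stats::runif(2, 0.2, 0.8))
      add(t_now + th + mv, "drop", drop_pos[1], drop_pos[2],
          zone = to_zone, index = to_index)
      t_now <<- t_now + th + mv
    }
    fruitless_passes <- 0L
    overlooked <- new.env(parent = emptyenv())
    repeat {
      if (is_won(state) || ne >= max_gestures ||
          fruitless_passes >= profile$persistence) break
      if (stats::runif(1) < profile$p_hint) {
        tap("hint_tap", 0.05, 0.05, scale = 0.3)
      }
      if (length(state$history) && stats::runif(1) < profile$p_undo) {
        tap("undo_tap", 0.12, 0.05, scale = 0.3)
        state <- apply_undo(state)
        next
      }
      if (stats::runif(1) < profile$p_error) {
        ill <- pick_illegal_move(state)
        if (!is.null(ill)) {
          pickup_drop(ill$card, ill$from, ill$to_zone, ill$to_index)
          next  # the app rejects the drop; state unchanged
        }
      }
      cand <- policy_moves(state)
      # Overlooking is sticky: a candidate missed once stays unperceived
      # until a successful move redraws attention to the board. This is what
      # makes the overlook probability genuinely lossy -- a stalled player
      # keeps missing the same pairing, accumulates fruitless passes through
      # the pile, and quits.
      perceived <- Filter(function(m) {
        sig <- paste(m$from_zone, m$from_index, m$to_zone, m$to_index, m$n_cards)
        if (!is.null(overlooked[[sig]])) return(FALSE)
        # spotting a movable run means checking every card in it against the
        # destination, so the miss probability compounds with run length
        p_miss <- 1 - (1 - profile$p_overlook)^m$n_cards
        if (stats::runif(1) < p_miss) {
          overlooked[[sig]] <<- TRUE
          return(FALSE)
        }
        TRUE
      }, cand)
      if (length(perceived)) {
        m <- perceived[[1L]]
        head_card <- switch(m$from_zone,
          talon = talon_top(state),
          build = {
            li <- length(state$build[[m$from_index]])
            state$build[[m$from_index]][li - m$n_cards + 1L]
          })
        pickup_drop(head_card, NULL, m$to_zone, m$to_index)
        state <- apply_relocation(state, m)
        fruitless_passes <- 0L
        overlooked <- new.env(parent = emptyenv())  # attention refreshes
      } else if (length(state$stock) || length(state$talon)) {
        recycling <- length(state$stock) == 0L
        tap("pile_tap", 0.95, 0.12, scale = 0.4)
        state <- apply_pile_flip(state)
        if (recycling) fruitless_passes <- fruitless_passes + 1L
      } else if (length(cand)) {
        # nothing to flip and every candidate overlooked: one fruitless scan
        fruitless_passes <- fruitless_passes + 1L
      } else {
        break  # no moves exist and nothing to flip: the game is dead
      }
    }
    events <- dplyr::bind_rows(lapply(ev[seq_len(ne)], tibble::as_tibble))
    if (!ne) events <- empty_events()
    event_log(participant_id = participant_id, game_index = game_index,
              seed = seed, draw_mode = draw_mode, events = events,
              card_geometry = geo)
  })
}

#' Default game seeds
#'
#' Three fixed deal seeds played by every simulated participant in order,
#' mirroring a design in which the order and games are identical across all
#' participants. The study's own deals are unpublished; these synthetic
#' stand-ins were selected by scanning seeds with a deterministic
#' non-overlooking agent and keeping the first three it could solve, so they
#' are solvable and differ in how much play they need.
#'
#' @export
default_game_seeds <- function() c(2L, 8L, 9L)

#' Draw participant covariates for one group
#'
#' Ages are drawn from the group-specific normal distributions of the
#' cohort reference (healthy: mean 70, SD 5.4; MCI: mean 80, SD 5.2), and
#' tablet / game proficiency ordinals (0 = never .. 4 = daily) from the
#' reference frequency tables. Uses the caller's RNG state.
#'
#' @param n Number of participants.
#' @param group `"healthy"` or `"mci"`.
#' @param id_prefix Prefix for participant ids.
#' @return A tibble of participant records.
#' @export
draw_participants <- function(n, group = c("healthy", "mci"),
                              id_prefix = NULL) {
  group <- match.arg(group)
  ref <- cohort_reference()
  a <- ref$age[ref$age$group == group, ]
  if (is.null(id_prefix)) id_prefix <- toupper(substr(group, 1, 1))
  tablet_probs <- ref$tablet[group, ]
  game_probs <- ref$game[group, ]
  tibble::tibble(
    participant_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    group = group,
    age = round(stats::rnorm(n, a$mean, a$sd), 1),
    tablet_proficiency = sample(0:4, n, replace = TRUE, prob = tablet_probs),
    game_proficiency = sample(0:4, n, replace = TRUE, prob = game_probs)
  )
}

# small per-participant deviations around the group profile
jitter_profile <- function(profile) {
  logit <- stats::qlogis; inv <- stats::plogis
  j <- profile
  j$think_mu <- profile$think_mu + stats::rnorm(1, 0, 0.15)
  j$move_mu <- profile$move_mu + stats::rnorm(1, 0, 0.10)
  j$p_overlook <- inv(logit(min(max(profile$p_overlook, 1e-3), 1 - 1e-3)) +
                        stats::rnorm(1, 0, 0.3))
  j$p_error <- inv(logit(min(max(profile$p_error, 1e-3), 1 - 1e-3)) +
                     stats::rnorm(1, 0, 0.3))
  j$tap_sd <- profile$tap_sd * exp(stats::rnorm(1, 0, 0.2))
  class(j) <- class(profile)
  j
}

#' Simulate a full cohort of gameplay logs
#'
#' Draws participant covariates per group, jitters the group profile per
#' participant, and lets every participant play the same game seeds in the
#' same order. Fully reproducible from `rng_seed`.
#'
#' @param n_healthy,n_mci Participants per group.
#' @param profiles Named list with `healthy` and `mci`
#'   [cognitive_profile()]s.
#' @param game_seeds Deal seeds, one game each, played in order.
#' @param rng_seed Master seed for covariates, profile jitter and gameplay.
#' @return A list with `participants` (tibble) and `logs` (list of
#'   `event_log`s, `n * length(game_seeds)` of them).
#' @export
generate_cohort <- function(n_healthy, n_mci,
                            profiles = list(healthy = healthy_profile(),
                                            mci = mci_profile()),
                            game_seeds = default_game_seeds(),
                            rng_seed = 1L) {
  stopifnot(n_healthy >= 1, n_mci >= 1)
  with_rng(rng_seed, {
    participants <- dplyr::bind_rows(
      draw_participants(n_healthy, "healthy"),
      draw_participants(n_mci, "mci")
    )
    logs <- vector("list", nrow(participants) * length(game_seeds))
    k <- 0L
    for (r in seq_len(nrow(participants))) {
      prof <- jitter_profile(profiles[[participants$group[r]]])
      for (g in seq_along(game_seeds)) {
        k <- k + 1L
        logs[[k]] <- simulate_game(
          prof, seed = game_seeds[g],
          rng_seed = sample.int(.Machine$integer.max - 1L, 1L),
          participant_id = participants$participant_id[r],
          game_index = g
        )
      }
    }
    list(participants = participants, logs = logs)
  })
}
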