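test_that("the registry defines exactly 23 biomarkers in 6 categories", {
  reg <- biomarker_registry()
  expect_identical(nrow(reg), 23L)
  expect_setequal(unique(reg$category),
                  c("time", "performance", "error", "execution",
                    "auxiliary", "result"))
  expect_length(unique(reg$category), 6)
  expect_identical(reg$related_pa[reg$biomarker == "think_time_avg"][[1]], 1L)
  expect_identical(reg$related_pa[reg$biomarker == "beta_error_pct"][[1]], 3:6)
  # binary biomarkers are modeled with the logit link, continuous with identity
  expect_identical(reg$link == "logit", reg$kind == "boolean")
  # uncaptured player actions never appear among the links
  expect_false(any(c(9L, 20L, 21L) %in% unlist(reg$related_pa)))
})

test_that("think and move times average over successful board gestures", {
  st <- klondike_deal(6)
  mv1 <- solitairebm:::relocations_list(st)[[1]]
  ev1 <- move_to_events(st, mv1, t_pickup = 2000, t_drop = 2500)
  st2 <- solitairebm:::apply_relocation(st, mv1)
  moves2 <- solitairebm:::relocations_list(st2)
  expect_gt(length(moves2), 0)
  ev2 <- move_to_events(st2, moves2[[1]], t_pickup = 6500, t_drop = 7000)
  log <- event_log("p", 1, seed = 6, events = dplyr::bind_rows(ev1, ev2))
  bm <- extract_biomarkers(log)
  expect_equal(bm$think_time_avg, 3000)   # (2000 + 4000) / 2
  expect_equal(bm$move_time_avg, 500)
  expect_equal(bm$total_time_avg, 3500)
  expect_equal(bm$cards_moved_avg, 1)
  expect_equal(bm$successful_move_pct, 100)
  expect_equal(bm$game_time, 7000)
})

test_that("beta error equals the share of flips made while a move was available", {
  # independent oracle: walk the raw events with the engine, querying the
  # brute-force relocation oracle before every pile tap
  log <- simulate_game(mci_profile(), seed = 8, rng_seed = 31)
  st <- klondike_deal(log$seed, log$draw_mode)
  ev <- log$events
  flips <- 0L; beta_flips <- 0L
  i <- 1L
  while (i <= nrow(ev)) {
    k <- ev$kind[i]
    if (k == "pile_tap") {
      flips <- flips + 1L
      if (length(oracle_relocations(st)) > 0) beta_flips <- beta_flips + 1L
      if (length(st$stock) || length(st$talon)) {
        st <- solitairebm:::apply_pile_flip(st)
      }
      i <- i + 1L
    } else if (k == "pickup") {
      loc <- solitairebm:::locate_card(st, ev$target_card[i])
      mv <- solitairebm:::mk_move("relocation", loc$zone, loc$index,
                                  ev$target_zone[i + 1L],
                                  ev$target_index[i + 1L], loc$n_cards)
      if (isTRUE(solitairebm:::check_relocation(st, mv))) {
        st <- solitairebm:::apply_relocation(st, mv)
      }
      i <- i + 2L
    } else {
      if (k == "undo_tap" && length(st$history)) {
        st <- solitairebm:::apply_undo(st)
      }
      i <- i + 1L
    }
  }
  expect_gt(flips, 0)
  bm <- extract_biomarkers(log)
  expect_equal(bm$beta_error_pct, 100 * beta_flips / flips)
})

test_that("a multi-card run contributes its length to cards moved", {
  log <- simulate_game(perfect_profile(), seed = 8, rng_seed = 1)
  rr <- replay(log)
  succ <- rr$gestures[rr$gestures$classification == "successful_board", ]
  expect_gt(max(succ$cards_moved), 1)   # a full game moves multi-card runs
  bm <- extract_biomarkers(rr)
  expect_equal(bm$cards_moved_avg, mean(succ$cards_moved))
  expect_equal(bm$cards_moved_sd, sd(succ$cards_moved))
  # cross-check one multi-card gesture against the raw event stream: the
  # pickup's card heads a run of exactly cards_moved cards at pickup time
  g_idx <- which(rr$gestures$cards_moved >= 2 &
                   rr$gestures$classification == "successful_board")[1]
  g <- rr$gestures[g_idx, ]
  st <- klondike_deal(log$seed, log$draw_mode)
  ev <- log$events
  i <- 1L
  while (i <= nrow(ev)) {
    if (ev$t[i] == g$t_start && ev$kind[i] == "pickup") {
      loc <- solitairebm:::locate_card(st, ev$target_card[i])
      expect_identical(loc$n_cards, g$cards_moved)
      break
    }
    if (ev$kind[i] == "pickup") {
      loc <- solitairebm:::locate_card(st, ev$target_card[i])
      mv <- solitairebm:::mk_move("relocation", loc$zone, loc$index,
                                  ev$target_zone[i + 1L],
                                  ev$target_index[i + 1L], loc$n_cards)
      if (isTRUE(solitairebm:::check_relocation(st, mv))) {
        st <- solitairebm:::apply_relocation(st, mv)
      }
      i <- i + 2L
    } else {
      if (ev$kind[i] == "pile_tap" && (length(st$stock) || length(st$talon))) {
        st <- solitairebm:::apply_pile_flip(st)
      } else if (ev$kind[i] == "undo_tap" && length(st$history)) {
        st <- solitairebm:::apply_undo(st)
      }
      i <- i + 1L
    }
  }
})

test_that("zero denominators yield NA biomarkers, not zeros", {
  ev <- tibble::tibble(t = 1000, kind = "stray_tap", x = 0.4, y = 0.4,
                       target_card = NA_integer_, target_zone = NA_character_,
                       target_index = NA_integer_)
  bm <- extract_biomarkers(event_log("p", 1, seed = 3, events = ev))
  expect_identical(bm$taps, 1L)
  expect_true(is.na(bm$beta_error_pct))       # no pile moves
  expect_true(is.na(bm$pile_move_pct))        # no board moves
  expect_true(is.na(bm$successful_move_pct))
  expect_true(is.na(bm$ace_beta_error_pct))   # no game moves
  expect_true(is.na(bm$undo_move_pct))
  expect_true(is.na(bm$think_time_avg))
  expect_error(extract_biomarkers(event_log("p", 1, seed = 3)), "no gestures")
})

test_that("extracted values respect the biomarker range invariants", {
  withr::with_seed(23, {
    profiles <- list(
      healthy_profile(), mci_profile(),
      cognitive_profile(p_overlook = 0.5, p_error = 0.2, tap_sd = 0.05,
                        p_undo = 0.05, p_hint = 0.05, stray_rate = 3,
                        persistence = 1L))
    for (prof in profiles) {
      for (rep in 1:4) {
        log <- simulate_game(prof, seed = sample(1:50, 1),
                             rng_seed = sample.int(1e6, 1))
        bm <- extract_biomarkers(log)
        pct_cols <- c("beta_error_pct", "ace_beta_error_pct",
                      "king_beta_error_pct", "pile_move_pct",
                      "successful_move_pct", "erroneous_move_pct",
                      "accuracy_avg", "undo_move_pct", "hint_move_pct")
        for (cc in pct_cols) {
          v <- bm[[cc]]
          if (!is.na(v)) expect_true(v >= 0 && v <= 100, label = cc)
        }
        sds <- c("think_time_sd", "move_time_sd", "total_time_sd",
                 "accuracy_sd", "cards_moved_sd")
        for (cc in sds) if (!is.na(bm[[cc]])) expect_gte(bm[[cc]], 0)
        # the attempt classes partition the board moves exactly
        if (!is.na(bm$successful_move_pct)) {
          expect_equal(bm$successful_move_pct + bm$erroneous_move_pct, 100)
        }
        expect_equal(bm$total_time_avg, bm$think_time_avg + bm$move_time_avg)
        rr <- replay(log)
        expect_gte(bm$game_time,
                   sum(rr$gestures$think_ms) + sum(rr$gestures$move_ms))
      }
    }
  })
})

test_that("raising the overlook probability raises beta errors and pile moves", {
  sim_means <- function(p_overlook, n, seed0) {
    prof <- cognitive_profile(p_overlook = p_overlook, p_error = 0.02,
                              persistence = 2L)
    bm <- purrr::map_dfr(seq_len(n), function(i) {
      extract_biomarkers(simulate_game(prof, seed = 2, rng_seed = seed0 + i))
    })
    bm
  }
  lo <- sim_means(0.05, 200, 10000)
  hi <- sim_means(0.35, 200, 20000)
  t_beta <- stats::t.test(hi$beta_error_pct, lo$beta_error_pct,
                          alternative = "greater")
  t_pile <- stats::t.test(hi$pile_move_pct, lo$pile_move_pct,
                          alternative = "greater")
  expect_lt(t_beta$p.value, 0.01)
  expect_lt(t_pile$p.value, 0.01)
})

test_that("cohort_table joins covariates to one row per game", {
  cohort <- generate_cohort(3, 2, game_seeds = c(2L, 8L), rng_seed = 77)
  tab <- cohort_table(cohort$logs, cohort$participants)
  expect_identical(nrow(tab), 10L)   # 5 participants x 2 games
  expect_true(all(c("group", "mci", "age", "tablet_proficiency",
                    "game_proficiency") %in% names(tab)))
  expect_identical(sort(unique(tab$mci)), c(0L, 1L))
  expect_true(all(biomarker_registry()$biomarker %in% names(tab)))
  # orphan log
  expect_error(cohort_table(cohort$logs, cohort$participants[-1, ]),
               "unknown participants")
  # empty inputs give an empty table with the full header
  empty <- cohort_table(list(), cohort$participants[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(all(biomarker_registry()$biomarker %in% names(empty)))
})
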