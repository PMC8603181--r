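test_that("tap accuracy is the normalized center-to-corner distance score", {
  rect <- c(0.5, 0.5, 0.03, 0.05)
  expect_equal(tap_accuracy(c(0.5, 0.5), rect), 100)
  expect_equal(tap_accuracy(c(0.53, 0.55), rect), 0)   # corner
  # edge midpoint: 100 * (1 - h / sqrt(w^2 + h^2))
  expect_equal(tap_accuracy(c(0.5, 0.55), rect),
               100 * (1 - 0.05 / sqrt(0.03^2 + 0.05^2)))
  # far-away taps clamp at 0 rather than going negative
  expect_equal(tap_accuracy(c(0.9, 0.9), rect), 0)
  expect_error(tap_accuracy(c(0.5, 0.5), c(0.5, 0.5, 0, 0.05)), "degenerate")
})

test_that("JSONL round trip reproduces a log field-for-field", {
  log <- simulate_game(mci_profile(), seed = 8, rng_seed = 99,
                       participant_id = "M0007", game_index = 2)
  expect_gt(nrow(log$events), 50)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, path)
  log2 <- read_event_log(path)
  expect_identical(log2$participant_id, log$participant_id)
  expect_identical(log2$game_index, log$game_index)
  expect_identical(log2$seed, log$seed)
  expect_identical(log2$draw_mode, log$draw_mode)
  expect_equal(as.data.frame(log2$events), as.data.frame(log$events))
  expect_equal(as.data.frame(log2$card_geometry),
               as.data.frame(log$card_geometry))
})

test_that("log validation names the violated rule", {
  ev <- tibble::tibble(t = c(100, 50), kind = c("stray_tap", "stray_tap"),
                       x = 0.5, y = 0.5, target_card = NA_integer_,
                       target_zone = NA_character_, target_index = NA_integer_)
  expect_error(event_log("p", 1, 1, events = ev), "nondecreasing")
  ev2 <- tibble::tibble(t = c(10, 20), kind = c("pickup", "pickup"),
                        x = 0.5, y = 0.5, target_card = 1L,
                        target_zone = NA_character_, target_index = NA_integer_)
  expect_error(event_log("p", 1, 1, events = ev2), "pair|alternate")
  ev3 <- tibble::tibble(t = 10, kind = "stray_tap", x = 0.5, y = 0.5,
                        target_card = 3L, target_zone = NA_character_,
                        target_index = NA_integer_)
  expect_error(event_log("p", 1, 1, events = ev3), "stray")
})

test_that("a truncated file reports a parse error with its line number", {
  log <- simulate_game(healthy_profile(), seed = 2, rng_seed = 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, path)
  lines <- readLines(path)
  n <- length(lines)
  lines[n] <- substr(lines[n], 1, 12)
  writeLines(lines, path)
  expect_error(read_event_log(path), sprintf("line %d", n))
})

test_that("replay of an empty log returns no gestures and the fresh deal", {
  log <- event_log("p", 1, seed = 42)
  rr <- replay(log)
  expect_identical(nrow(rr$gestures), 0L)
  expect_true(state_equal(rr$final_state, klondike_deal(42)))
})

test_that("an illegal drop is classified erroneous and leaves the state unchanged", {
  st <- klondike_deal(6)
  # find a build top and a destination where its placement is illegal
  tops <- vapply(1:7, function(j) {
    b <- st$build[[j]]
    if (length(b)) b[length(b)] else NA_integer_
  }, integer(1))
  found <- FALSE
  for (i in which(!is.na(tops))) {
    for (j in setdiff(which(!is.na(tops)), i)) {
      mv <- list(kind = "relocation", from_zone = "build", from_index = i,
                 to_zone = "build", to_index = j, n_cards = 1L)
      if (!isTRUE(solitairebm:::check_relocation(st, mv))) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  ev <- move_to_events(st, mv, t_pickup = 1000, t_drop = 1600)
  rr <- replay(event_log("p", 1, seed = 6, events = ev))
  expect_identical(rr$gestures$classification, "erroneous_board")
  expect_true(state_equal(rr$final_state, st))
  # timing: think from t = 0 to pickup, move from pickup to drop
  expect_equal(rr$gestures$think_ms, 1000)
  expect_equal(rr$gestures$move_ms, 600)
})

test_that("a drop at its origin is a neutral gesture", {
  st <- klondike_deal(6)
  top1 <- st$build[[1]][1]
  ev <- tibble::tibble(
    t = c(500, 900), kind = c("pickup", "drop"), x = 0.5, y = 0.5,
    target_card = c(top1, NA_integer_),
    target_zone = c(NA_character_, "build"),
    target_index = c(NA_integer_, 1L))
  rr <- replay(event_log("p", 1, seed = 6, events = ev))
  expect_identical(rr$gestures$classification, "neutral_board")
  expect_true(state_equal(rr$final_state, st))
})

test_that("a pile tap in draw-1 mode moves one card from stock to talon", {
  ev <- tibble::tibble(t = 800, kind = "pile_tap", x = 0.95, y = 0.1,
                       target_card = NA_integer_, target_zone = NA_character_,
                       target_index = NA_integer_)
  rr <- replay(event_log("p", 1, seed = 9, events = ev))
  expect_length(rr$final_state$stock, 23)
  expect_length(rr$final_state$talon, 1)
  expect_identical(rr$gestures$classification, "pile")
  expect_equal(rr$gestures$move_ms, 0)
})

test_that("replay is deterministic and classifications partition the gestures", {
  log <- simulate_game(mci_profile(), seed = 2, rng_seed = 17)
  rr1 <- replay(log)
  rr2 <- replay(log)
  expect_equal(as.data.frame(rr1$gestures), as.data.frame(rr2$gestures))
  expect_true(state_equal(rr1$final_state, rr2$final_state))
  classes <- c("successful_board", "erroneous_board", "neutral_board",
               "pile", "undo", "hint", "stray")
  expect_true(all(rr1$gestures$classification %in% classes))
  expect_identical(sum(table(rr1$gestures$classification)),
                   as.integer(nrow(rr1$gestures)))
  # per-gesture times cannot exceed the total logged game time
  expect_lte(sum(rr1$gestures$think_ms) + sum(rr1$gestures$move_ms),
             max(log$events$t))
})

test_that("pickup tap accuracy is measured against the picked card's rectangle", {
  st <- klondike_deal(6)
  mv <- solitairebm:::relocations_list(st)[[1]]
  geo <- default_card_geometry()
  ev <- move_to_events(st, mv, 400, 700, geometry = geo)
  rr <- replay(event_log("p", 1, seed = 6, events = ev))
  expect_equal(rr$gestures$tap_accuracy, 100)  # move_to_events taps dead center
})
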