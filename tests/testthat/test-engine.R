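test_that("deal lays out 28 build cards and a 24-card stock, deterministically", {
  for (seed in c(1, 7, 123, 99991)) {
    st <- klondike_deal(seed)
    expect_identical(lengths(st$build), 1:7)
    expect_identical(st$face_up, rep(1L, 7))
    expect_length(st$stock, 24)
    expect_length(st$talon, 0)
    expect_identical(st$foundation, rep(0L, 4))
    expect_identical(st$score, 0L)
    expect_setequal(c(unlist(st$build), st$stock), 1:52)
    expect_true(state_equal(st, klondike_deal(seed)))
  }
  expect_false(state_equal(klondike_deal(1), klondike_deal(2)))
})

test_that("build destinations follow the rank-down opposite-color rule", {
  six_spades <- 45L; five_hearts <- 31L; five_clubs <- 5L
  rest <- setdiff(1:52, c(six_spades, five_hearts))
  st <- make_state(build = c(list(six_spades),
                             lapply(1:6, function(i) integer(0))),
                   face_up = c(1L, rep(0L, 6)),
                   stock = rest, talon = five_hearts)
  mv <- legal_moves(st)
  expect_true(any(mv$kind == "relocation" & mv$from_zone == "talon" &
                    mv$to_zone == "build" & mv$to_index == 1))
  # a black 5 (clubs) may not go on the black 6
  st2 <- make_state(build = c(list(six_spades),
                              lapply(1:6, function(i) integer(0))),
                    face_up = c(1L, rep(0L, 6)),
                    stock = setdiff(1:52, c(six_spades, five_clubs)),
                    talon = five_clubs)
  expect_error(
    apply_move(st2, list(kind = "relocation", from_zone = "talon",
                         from_index = 0L, to_zone = "build", to_index = 1L,
                         n_cards = 1L)),
    "color")
  expect_false(any(move_signature(legal_moves(st2)) ==
                     "relocation talon 0 build 1 1"))
})

test_that("an empty build stack accepts only a king-headed run", {
  # stack 1 empty; stack 2 holds a face-up king of diamonds over a hidden card
  hidden <- 5L
  st <- make_state(build = c(list(integer(0), c(hidden, 26L)),
                             lapply(1:5, function(i) integer(0))),
                   face_up = c(0L, 1L, rep(0L, 5)),
                   stock = setdiff(1:52, c(hidden, 26L)))
  mv <- legal_moves(st)
  expect_true(any(mv$from_zone == "build" & mv$from_index == 2 &
                    mv$to_index == 1, na.rm = TRUE))
  # a non-king cannot fill the empty stack
  st2 <- make_state(build = c(list(integer(0), c(hidden, 30L)),
                              lapply(1:5, function(i) integer(0))),
                    face_up = c(0L, 1L, rep(0L, 5)),
                    stock = setdiff(1:52, c(hidden, 30L)))
  mv2 <- legal_moves(st2)
  expect_false(any(mv2$to_zone == "build" & mv2$to_index == 1, na.rm = TRUE))
})

test_that("legal-move enumeration matches the brute-force oracle on random states", {
  withr::with_seed(42, {
    for (i in 1:300) {
      st <- random_mid_state(seed = i, k = sample(5:60, 1))
      expect_identical(move_signature(legal_moves(st)),
                       oracle_relocations(st))
    }
  })
})

test_that("apply_move updates zones, score and win state correctly", {
  st <- klondike_deal(3)
  st2 <- apply_move(st, list(kind = "pile_flip"))
  expect_length(st2$stock, 23)
  expect_length(st2$talon, 1)
  mv <- legal_moves(st2)
  reloc <- mv[mv$kind == "relocation" & mv$from_zone == "talon", ]
  if (nrow(reloc)) {
    st3 <- apply_move(st2, reloc[1, ])
    expect_length(st3$talon, 0)
    expect_identical(st3$move_count, st2$move_count + 1L)
  }
  # one relocation from a finished game
  near <- make_state(
    build = c(list(52L), lapply(1:6, function(i) integer(0))),
    face_up = c(1L, rep(0L, 6)),
    foundation = c(13L, 13L, 13L, 12L))
  expect_false(is_won(near))
  won <- apply_move(near, list(kind = "relocation", from_zone = "build",
                               from_index = 1L, to_zone = "suit",
                               to_index = 4L, n_cards = 1L))
  expect_true(is_won(won))
  expect_identical(won$score, 10L)
  # 51 cards on the foundations is not a win
  expect_false(is_won(near))
})

test_that("undo restores the prior position exactly, score included", {
  withr::with_seed(7, {
    for (i in 1:25) {
      st <- random_mid_state(seed = 100 + i, k = sample(0:40, 1))
      moves <- solitairebm:::legal_moves_list(st)
      if (!length(moves)) next
      mv <- moves[[sample.int(length(moves), 1)]]
      st2 <- apply_move(st, mv)
      st3 <- apply_move(st2, list(kind = "undo"))
      expect_true(state_equal(st, st3))
    }
  })
  expect_error(apply_move(klondike_deal(1), list(kind = "undo")), "history")
})

test_that("cards are conserved and foundations only shrink via worried moves", {
  withr::with_seed(11, {
    st <- klondike_deal(17)
    prev_foundation <- sum(st$foundation)
    for (step in 1:150) {
      moves <- solitairebm:::legal_moves_list(st)
      if (!length(moves)) break
      mv <- moves[[sample.int(length(moves), 1)]]
      st <- apply_move(st, mv)
      validate_state(st)  # includes exact 52-card multiset equality
      f <- sum(st$foundation)
      if (f < prev_foundation) {
        expect_identical(mv$kind, "relocation")
        expect_identical(mv$from_zone, "suit")
      }
      prev_foundation <- f
    }
    founds <- unlist(lapply(1:4, function(s) {
      if (st$foundation[s] > 0) (s - 1) * 13 + seq_len(st$foundation[s])
    }))
    expect_setequal(c(unlist(st$build), founds, st$stock, st$talon), 1:52)
  })
})

test_that("opportunity report agrees with the legal-move enumeration", {
  withr::with_seed(5, {
    for (i in 1:50) {
      st <- random_mid_state(seed = 200 + i, k = sample(0:50, 1))
      opp <- playable_opportunities(st)
      expect_identical(opp$any_board_move,
                       length(oracle_relocations(st)) > 0)
      if (!any(lengths(st$build) == 0)) {
        expect_false(opp$king_playable_to_empty)
      }
      tops <- c(vapply(1:7, function(j) {
        b <- st$build[[j]]
        if (length(b)) b[length(b)] else NA_integer_
      }, integer(1)), if (length(st$talon)) st$talon[length(st$talon)])
      expect_identical(opp$ace_playable,
                       any(card_rank(tops[!is.na(tops)]) == 1))
    }
  })
})

test_that("invalid states are rejected with the violated rule", {
  st <- klondike_deal(1)
  st$stock <- st$stock[-1]
  expect_error(legal_moves(st), "52-card")
  st2 <- klondike_deal(1)
  st2$face_up[3] <- 0L
  expect_error(validate_state(st2), "face-up")
})
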