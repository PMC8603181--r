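# Card encoding: a card is an integer 1..52.
# suit = (id - 1) %/% 13 + 1 in the order clubs, diamonds, hearts, spades;
# rank = (id - 1) %% 13 + 1 with 1 = ace and 13 = king.

SUITS <- c("clubs", "diamonds", "hearts", "spades")
RANK_LABELS <- c("A", as.character(2:10), "J", "Q", "K")

#' Card attributes
#'
#' Cards are encoded as integers `1:52`, grouped by suit in the order clubs,
#' diamonds, hearts, spades, and within suit ordered ace (1) to king (13).
#' Diamonds and hearts are red; clubs and spades are black.
#'
#' @param card Integer vector of card ids in `1:52`.
#' @return `card_rank()` returns integer ranks in `1:13`; `card_suit()` the
#'   suit name; `card_color()` `"red"` or `"black"`; `card_label()` a compact
#'   label such as `"QH"` (queen of hearts).
#' @examples
#' card_label(full_deck())[1:13]
#' @export
card_rank <- function(card) {
  stopifnot(all(card >= 1L & card <= 52L))
  (as.integer(card) - 1L) %% 13L + 1L
}

#' @rdname card_rank
#' @export
card_suit <- function(card) {
  stopifnot(all(card >= 1L & card <= 52L))
  SUITS[(as.integer(card) - 1L) %/% 13L + 1L]
}

#' @rdname card_rank
#' @export
card_color <- function(card) {
  ifelse(card_suit(card) %in% c("diamonds", "hearts"), "red", "black")
}

#' @rdname card_rank
#' @export
card_label <- function(card) {
  paste0(RANK_LABELS[card_rank(card)], c(clubs = "C", diamonds = "D",
                                         hearts = "H", spades = "S")[card_suit(card)])
}

#' @rdname card_rank
#' @export
full_deck <- function() 1:52

# id of the card with a given rank (1..13) and suit index (1..4)
card_id <- function(rank, suit_index) (suit_index - 1L) * 13L + as.integer(rank)

# suit index 1..4 from a card id
suit_index <- function(card) (as.integer(card) - 1L) %/% 13L + 1L

# TRUE where the two cards have opposite colors
opposite_color <- function(a, b) {
  red <- function(x) {
    s <- (as.integer(x) - 1L) %/% 13L + 1L
    s == 2L | s == 3L
  }
  xor(red(a), red(b))
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% (.Machine$integer.max - 1)),
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}
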