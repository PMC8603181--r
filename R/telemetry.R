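# Event-log format and serialization.
#
# A log is one participant-game: a header (participant, game index, seed,
# draw mode, per-card touch geometry) plus a time-ordered gesture stream.
# Coordinates are normalized to [0,1]^2 with the origin top-left, so nothing
# downstream depends on device pixels. File format is JSON Lines (header
# object first, one event per line), schema "sollog/1".

EVENT_KINDS <- c("pickup", "drop", "pile_tap", "undo_tap", "hint_tap", "stray_tap")

#' Construct and validate an event log
#'
#' @param participant_id Participant identifier string.
#' @param game_index Game number within the session (1..3 in the study design).
#' @param seed Game seed; with `draw_mode` it reproduces the deal exactly.
#' @param draw_mode `"draw1"` or `"draw3"`.
#' @param events Tibble of gestures with columns `t` (ms from game start,
#'   nondecreasing), `kind` (one of pickup, drop, pile_tap, undo_tap,
#'   hint_tap, stray_tap), `x`, `y` (normalized tap position), `target_card`
#'   (card id, pickups only), `target_zone`, `target_index` (drops only).
#' @param card_geometry Per-card touch rectangles: tibble with `card`, `cx`,
#'   `cy` (center) and `hx`, `hy` (half-extents), all in normalized units.
#' @return An `event_log` object.
#' @export
event_log <- function(participant_id, game_index, seed,
                      draw_mode = "draw1", events = empty_events(),
                      card_geometry = default_card_geometry()) {
  log <- structure(
    list(schema = "sollog/1",
         participant_id = as.character(participant_id),
         game_index = as.integer(game_index),
         seed = as.integer(seed),
         draw_mode = draw_mode,
         card_geometry = tibble::as_tibble(card_geometry),
         events = tibble::as_tibble(events)),
    class = "event_log"
  )
  validate_event_log(log)
}

#' @rdname event_log
#' @export
empty_events <- function() {
  tibble::tibble(t = numeric(), kind = character(), x = numeric(),
                 y = numeric(), target_card = integer(),
                 target_zone = character(), target_index = integer())
}

#' Default per-card touch geometry
#'
#' Lays the 52 cards out on a 13 x 4 grid of touch rectangles with
#' half-extents `hx`, `hy`. The geometry is a stand-in for device-reported
#' card rectangles; only the rectangle of the touched card matters to the
#' accuracy biomarker, not where it sits on screen.
#'
#' @param hx,hy Rectangle half-extents in normalized screen units.
#' @export
default_card_geometry <- function(hx = 0.034, hy = 0.048) {
  card <- 1:52
  tibble::tibble(
    card = card,
    cx = (card_rank(card) - 0.5) / 13,
    cy = (suit_index(card) - 0.5) / 4,
    hx = hx, hy = hy
  )
}

#' @rdname event_log
#' @param log An `event_log`.
#' @export
validate_event_log <- function(log) {
  ev <- log$events
  fail <- function(rule) stop(sprintf("invalid event log: %s", rule), call. = FALSE)
  if (!all(c("t", "kind", "x", "y", "target_card", "target_zone",
             "target_index") %in% names(ev))) fail("missing event columns")
  if (!log$game_index >= 1L) fail("game_index must be >= 1")
  if (nrow(ev)) {
    if (any(!ev$kind %in% EVENT_KINDS)) fail("unknown event kind")
    if (any(ev$t < 0)) fail("negative timestamp")
    if (any(diff(ev$t) < 0)) fail("timestamps must be nondecreasing")
    pickups <- ev$kind == "pickup"
    drops <- ev$kind == "drop"
    if (sum(pickups) != sum(drops)) fail("pickups and drops must pair up")
    depth <- cumsum(pickups) - cumsum(drops)
    if (any(depth > 1L) || any(depth < 0L)) fail("pickups and drops must alternate")
    mid_drag <- depth == 1L & !pickups   # events issued during a drag
    if (any(mid_drag & !drops)) fail("taps cannot occur during a drag")
    if (any(pickups & is.na(ev$target_card))) fail("pickup without a card target")
    if (any(drops & is.na(ev$target_zone))) fail("drop without a zone target")
    if (any(ev$kind == "stray_tap" &
            (!is.na(ev$target_card) | !is.na(ev$target_zone)))) {
      fail("stray taps carry no target")
    }
  }
  geo <- log$card_geometry
  if (!all(1:52 %in% geo$card)) fail("card_geometry must cover all 52 cards")
  if (any(geo$hx <= 0 | geo$hy <= 0)) fail("degenerate card rectangle")
  invisible(log)
}

#' Tap accuracy
#'
#' How close to the center of its touch rectangle a card was touched:
#' `100 * (1 - d / d_max)` clamped to `[0, 100]`, where `d` is the Euclidean
#' distance from the tap to the rectangle center and `d_max` the
#' center-to-corner distance, so a dead-center tap scores 100 and a corner
#' tap 0.
#'
#' @param pos Numeric length-2 tap position `(x, y)`.
#' @param rect Rectangle as `c(cx, cy, hx, hy)` (center + half-extents).
#' @return Accuracy percentage in `[0, 100]`.
#' @examples
#' tap_accuracy(c(0.5, 0.5), c(0.5, 0.5, 0.04, 0.06))  # 100
#' @export
tap_accuracy <- function(pos, rect) {
  if (rect[3] <= 0 || rect[4] <= 0) {
    stop("degenerate card rectangle", call. = FALSE)
  }
  d <- sqrt((pos[1] - rect[1])^2 + (pos[2] - rect[2])^2)
  d_max <- sqrt(rect[3]^2 + rect[4]^2)
  min(100, max(0, 100 * (1 - d / d_max)))
}

#' Write / read an event log as JSON Lines
#'
#' One object per line: a header first (schema, participant, game index,
#' seed, draw mode, card geometry), then the events in order. `read_event_log()`
#' inverts `write_event_log()` field-for-field and errors with the offending
#' line number on malformed input, then re-validates the log invariants.
#'
#' @param log An `event_log`.
#' @param path File path.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  geo <- log$card_geometry
  geo_list <- stats::setNames(
    lapply(seq_len(nrow(geo)), function(i) unname(unlist(geo[i, c("cx", "cy", "hx", "hy")]))),
    as.character(geo$card)
  )
  header <- list(schema = log$schema, participant_id = log$participant_id,
                 game_index = log$game_index, seed = log$seed,
                 draw_mode = log$draw_mode, card_geometry = geo_list)
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  ev <- log$events
  if (nrow(ev)) {
    ev_lines <- vapply(seq_len(nrow(ev)), function(i) {
      e <- list(t = ev$t[i], kind = ev$kind[i], pos = c(ev$x[i], ev$y[i]))
      if (!is.na(ev$target_card[i])) e$target <- list(card = ev$target_card[i])
      if (!is.na(ev$target_zone[i])) {
        e$target <- list(zone = ev$target_zone[i], index = ev$target_index[i])
      }
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA))
    }, character(1))
    lines <- c(lines, ev_lines)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @param source Path to a JSONL event-log file.
#' @export
read_event_log <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (!length(lines)) stop("empty event-log file", call. = FALSE)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) {
               stop(sprintf("parse error at line %d of '%s': %s", i, source,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  header <- parse_line(1L)
  geo_raw <- header$card_geometry
  geo <- tibble::tibble(
    card = as.integer(names(geo_raw)),
    cx = vapply(geo_raw, `[`, numeric(1), 1L),
    cy = vapply(geo_raw, `[`, numeric(1), 2L),
    hx = vapply(geo_raw, `[`, numeric(1), 3L),
    hy = vapply(geo_raw, `[`, numeric(1), 4L)
  )
  geo <- geo[order(geo$card), ]
  n_ev <- length(lines) - 1L
  ev <- lapply(seq_len(n_ev), function(k) {
    e <- parse_line(k + 1L)
    tibble::tibble(
      t = as.numeric(e$t), kind = e$kind,
      x = as.numeric(e$pos[1]), y = as.numeric(e$pos[2]),
      target_card = if (!is.null(e$target$card)) as.integer(e$target$card) else NA_integer_,
      target_zone = if (!is.null(e$target$zone)) e$target$zone else NA_character_,
      target_index = if (!is.null(e$target$index)) as.integer(e$target$index) else NA_integer_
    )
  })
  events <- if (n_ev) dplyr::bind_rows(ev) else empty_events()
  event_log(participant_id = header$participant_id,
            game_index = header$game_index, seed = header$seed,
            draw_mode = header$draw_mode, events = events,
            card_geometry = geo)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %s game %d, seed %d (%s), %d events\n",
              x$participant_id, x$game_index, x$seed, x$draw_mode,
              nrow(x$events)))
  invisible(x)
}
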