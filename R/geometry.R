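#' Build a trap tibble from centres
#'
#' Traps are closed axis-aligned squares. Used internally by the scenario
#' builders; exported because hand-built trap sets are handy in tests and
#' small experiments.
#'
#' @param x,y Trap centre coordinates (units).
#' @param side Square side length (units), default 2.
#' @param trap_id Optional character labels; defaults to `"T<i>"` ordinals.
#' @param row,col Optional integer grid indices (0-based) carried along.
#' @return A tibble with columns `trap_id`, `row`, `col`, `x`, `y`, `side`.
#' @export
make_traps <- function(x, y, side = 2, trap_id = NULL, row = NA_integer_,
                       col = NA_integer_) {
  stopifnot(length(x) == length(y), all(side > 0))
  if (is.null(trap_id)) trap_id <- paste0("T", seq_along(x))
  traps <- tibble::tibble(
    trap_id = as.character(trap_id),
    row = as.integer(row), col = as.integer(col),
    x = as.numeric(x), y = as.numeric(y), side = as.numeric(side)
  )
  assert_no_overlap(traps)
  traps
}

# pairwise non-overlap of closed squares (touching edges count as overlap)
assert_no_overlap <- function(traps) {
  n <- nrow(traps)
  if (n < 2) return(invisible(traps))
  h <- traps$side / 2
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    ovl <- abs(traps$x[j] - traps$x[i]) <= h[j] + h[i] &
      abs(traps$y[j] - traps$y[i]) <= h[j] + h[i]
    if (any(ovl)) {
      stop("traps overlap: ", traps$trap_id[i], " and ",
           traps$trap_id[j[which(ovl)[1]]], call. = FALSE)
    }
  }
  invisible(traps)
}

# matrix of [xmin, xmax, ymin, ymax] rows for the C++ engine
trap_bounds <- function(traps) {
  h <- traps$side / 2
  cbind(traps$x - h, traps$x + h, traps$y - h, traps$y + h)
}

point_in_traps <- function(x, y, traps) {
  b <- trap_bounds(traps)
  out <- logical(length(x))
  for (j in seq_len(nrow(b))) {
    out <- out | (x >= b[j, 1] & x <= b[j, 2] & y >= b[j, 3] & y <= b[j, 4])
  }
  out
}

#' Advance a mover by one step
#'
#' The new heading is the old heading plus the turn (mod 360); the mover
#' then moves exactly `step_length` units along the new heading.
#'
#' @param x,y Current position.
#' @param heading_deg Current heading, degrees.
#' @param turn_deg Turn to apply, degrees (positive = counter-clockwise).
#' @param step_length Step length (units), > 0.
#' @return A list with `x`, `y`, `heading_deg` (wrapped into [0, 360)).
#' @export
advance_step <- function(x, y, heading_deg, turn_deg, step_length = 1) {
  stopifnot(step_length > 0)
  h <- (heading_deg + turn_deg) %% 360
  rad <- h * pi / 180
  list(x = x + step_length * cos(rad),
       y = y + step_length * sin(rad),
       heading_deg = h)
}

#' First trap intersected by a step segment
#'
#' Tests the whole movement segment against each closed trap square (not
#' just the endpoint), so a step that clips a trap corner still captures.
#' When the segment crosses several traps the one entered first (entry
#' point nearest the segment start) wins.
#'
#' @param x0,y0 Segment start.
#' @param x1,y1 Segment end.
#' @param traps Trap tibble from [make_traps()] or a scenario builder.
#' @return The `trap_id` of the first trap hit, or `NA_character_`.
#' @export
detect_capture <- function(x0, y0, x1, y1, traps) {
  hit <- segment_trap_hit_cpp(as.numeric(x0), as.numeric(y0),
                              as.numeric(x1), as.numeric(y1),
                              trap_bounds(traps))
  ifelse(hit == 0L, NA_character_, traps$trap_id[pmax(hit, 1L)])
}
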