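#' @title Simulation scenarios
#' @description
#' A scenario bundles trap geometry with a release specification. Three
#' builders cover the study designs used throughout the package:
#' a corner release outside a 5 x 5 grid (the trapping-grid design a field
#' mark-release-recapture mirrors), a centre release inside a 7 x 7 grid
#' (high target density), and a single trap in a large seeding arena (low
#' target density).
#'
#' Coordinates are continuous Cartesian with the origin at the centre of
#' trap (row 0, col 0); rows increase along +y and columns along +x.
#' @name scenarios
NULL

new_scenario <- function(name, traps, release) {
  # release points must be outside every trap
  if (release$mode == "point" &&
      point_in_traps(release$x, release$y, traps)) {
    stop("release point lies inside a trap", call. = FALSE)
  }
  structure(list(name = name, traps = traps, release = release),
            class = "trap_scenario")
}

#' @export
print.trap_scenario <- function(x, ...) {
  cat("<trap_scenario> ", x$name, ": ", nrow(x$traps), " trap(s), release mode '",
      x$release$mode, "'\n", sep = "")
  invisible(x)
}

grid_traps <- function(n_rows, n_cols, spacing, trap_side) {
  if (spacing <= trap_side) {
    stop("`spacing` must exceed `trap_side` (non-overlapping traps)",
         call. = FALSE)
  }
  g <- expand.grid(row = 0:(n_rows - 1), col = 0:(n_cols - 1))
  make_traps(x = g$col * spacing, y = g$row * spacing, side = trap_side,
             trap_id = sprintf("r%dc%d", g$row, g$col),
             row = g$row, col = g$col)
}

#' Corner-release trapping grid
#'
#' An `n` x `n` lattice of square traps with the release point on the grid
#' diagonal, `release_offset` units outward from the centre of the corner
#' trap (row 0, col 0). The diagonal placement preserves the left/right
#' symmetry of the two grid edges adjacent to the release corner, which the
#' edge-trap pairing of [label_edge_traps()] relies on.
#'
#' @param n Traps per side (default 5).
#' @param spacing Centre-to-centre trap distance, units (default 15).
#' @param trap_side Trap square side, units (default 2).
#' @param release_offset Distance from corner-trap centre to the release
#'   point, units (default 10).
#' @return A `trap_scenario`.
#' @export
#' @examples
#' sc <- scenario_corner_release()
#' nrow(sc$traps)
scenario_corner_release <- function(n = 5, spacing = 15, trap_side = 2,
                                    release_offset = 10) {
  stopifnot(n >= 1, release_offset > 0)
  if (release_offset <= trap_side / 2 * sqrt(2)) {
    stop("`release_offset` places the release point inside the corner trap",
         call. = FALSE)
  }
  traps <- if (n == 1) {
    make_traps(0, 0, side = trap_side, trap_id = "r0c0", row = 0L, col = 0L)
  } else {
    grid_traps(n, n, spacing, trap_side)
  }
  r <- release_offset / sqrt(2)
  new_scenario("corner5x5",
               traps,
               list(mode = "point", x = -r, y = -r, corner = "NW"))
}

#' Centre-release trapping grid
#'
#' An `n` x `n` lattice with the release point offset half a spacing along
#' +x from the central trap's centre ("near the centre" but outside every
#' trap). With the defaults (7 x 7, spacing 20) each trap serves about one
#' 300-square-unit cell of the grid: the high-target-density design.
#'
#' @inheritParams scenario_corner_release
#' @param n Traps per side; must be odd so a central trap exists (default 7).
#' @param spacing Centre-to-centre trap distance, units (default 20).
#' @param release_offset Offset of the release point from the central trap
#'   centre along +x, units (default `spacing / 2`).
#' @return A `trap_scenario`.
#' @export
scenario_center_release <- function(n = 7, spacing = 20, trap_side = 2,
                                    release_offset = spacing / 2) {
  stopifnot(n >= 1, n %% 2 == 1)
  traps <- grid_traps(n, n, spacing, trap_side)
  c0 <- (n - 1) / 2 * spacing
  new_scenario("center7x7",
               traps,
               list(mode = "point", x = c0 + release_offset, y = c0))
}

#' Single-trap low-density arena
#'
#' One square trap at the centre of a `arena_w` x `arena_h` seeding
#' rectangle; movers are seeded uniformly over the rectangle (rejecting
#' points inside the trap) and range in unbounded space. With the defaults
#' the target density is one trap per 600,000 square units.
#'
#' @param arena_w,arena_h Seeding rectangle width and height, units.
#' @param trap_side Trap square side, units (default 2).
#' @return A `trap_scenario`; the release rectangle has its lower-left
#'   corner at the origin.
#' @export
scenario_low_density <- function(arena_w = 1000, arena_h = 600,
                                 trap_side = 2) {
  stopifnot(arena_w > trap_side, arena_h > trap_side)
  traps <- make_traps(arena_w / 2, arena_h / 2, side = trap_side,
                      trap_id = "T1")
  new_scenario("lowdensity",
               traps,
               list(mode = "uniform", xmin = 0, xmax = arena_w,
                    ymin = 0, ymax = arena_h))
}

# initial positions for one run (uniform mode rejects points inside traps)
release_positions <- function(scenario, n_movers) {
  rel <- scenario$release
  if (rel$mode == "point") {
    return(list(x = rep(rel$x, n_movers), y = rep(rel$y, n_movers)))
  }
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n_movers) {
    m <- n_movers - length(x)
    cx <- stats::runif(m, rel$xmin, rel$xmax)
    cy <- stats::runif(m, rel$ymin, rel$ymax)
    keep <- !point_in_traps(cx, cy, scenario$traps)
    x <- c(x, cx[keep]); y <- c(y, cy[keep])
  }
  list(x = x, y = y)
}

#' Tabulate scenario geometry
#'
#' @param x A `trap_scenario`.
#' @param ... Unused.
#' @return The trap tibble (`trap_id`, `row`, `col`, `x`, `y`, `side`),
#'   suitable for a geometry CSV.
#' @export
#' @method tidy trap_scenario
tidy.trap_scenario <- function(x, ...) x$traps
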