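#' Simulate a population of correlated random walkers
#'
#' Each mover starts at a release position with an independent uniform
#' initial heading, takes its first step of `step_length` units on that
#' heading, and thereafter turns by an independent Gaussian angle of
#' circular standard deviation `csd_deg` before every step. Space is
#' unbounded; any mover whose step segment touches a trap square is held
#' there (absorbing traps) and counted against that trap. Captured movers
#' stop at the point where their path first enters the trap.
#'
#' @param scenario A `trap_scenario` from one of the scenario builders.
#' @param csd_deg Circular standard deviation of turn angles, degrees.
#' @param n_movers Population size (default 400).
#' @param n_steps Steps per mover (default 400).
#' @param step_length Units per step (default 1).
#' @param seed Optional integer seed; when given the run is fully
#'   reproducible (`set.seed()` is applied inside a local RNG scope).
#' @param capture_mode `"segment"` (default) tests the whole step segment
#'   against each trap; `"endpoint"` tests only the step's end point (the
#'   faster, tunnelling-prone variant, kept for sensitivity comparisons).
#' @return A `crw_sim` object: a list with
#'   \describe{
#'     \item{catches}{tibble `trap_id`, `row`, `col`, `x`, `y`, `catch`;}
#'     \item{movers}{tibble of per-mover final state (`x`, `y`,
#'       `heading_deg`, `captured_by`, `capture_step`);}
#'     \item{params}{echo of all simulation parameters.}
#'   }
#' @export
#' @examples
#' sim <- simulate_walkers(scenario_corner_release(), csd_deg = 30,
#'                         n_movers = 50, n_steps = 100, seed = 1)
#' sum(sim$catches$catch)
simulate_walkers <- function(scenario, csd_deg, n_movers = 400,
                             n_steps = 400, step_length = 1, seed = NULL,
                             capture_mode = c("segment", "endpoint")) {
  stopifnot(inherits(scenario, "trap_scenario"),
            n_movers >= 1, n_steps >= 0, step_length > 0)
  capture_mode <- match.arg(capture_mode)
  if (csd_deg < 0) stop("`csd_deg` must be >= 0", call. = FALSE)

  run <- function() {
    pos <- release_positions(scenario, n_movers)
    if (any(point_in_traps(pos$x, pos$y, scenario$traps))) {
      stop("release position lies inside a trap", call. = FALSE)
    }
    crw_run_cpp(pos$x, pos$y, as.integer(n_steps), step_length, csd_deg,
                trap_bounds(scenario$traps), capture_mode == "segment")
  }
  res <- if (is.null(seed)) run() else with_local_seed(seed, run())

  traps <- scenario$traps
  catch <- tabulate(res$captured_by, nbins = nrow(traps))
  free <- res$captured_by == 0L

  structure(list(
    catches = dplyr::mutate(traps, catch = as.integer(catch)),
    movers = tibble::tibble(
      x = res$x, y = res$y,
      heading_deg = res$heading_deg %% 360,
      captured_by = ifelse(free, NA_character_,
                           traps$trap_id[pmax(res$captured_by, 1L)]),
      capture_step = res$capture_step
    ),
    params = list(scenario = scenario$name, csd_deg = csd_deg,
                  n_movers = n_movers, n_steps = n_steps,
                  step_length = step_length, seed = seed,
                  capture_mode = capture_mode)
  ), class = "crw_sim")
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive n child seeds (< 2^31) from one master seed
spawn_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @export
print.crw_sim <- function(x, ...) {
  cat("<crw_sim> ", x$params$scenario, ": ", x$params$n_movers, " movers x ",
      x$params$n_steps, " steps, c.s.d. ", x$params$csd_deg, " deg; captured ",
      sum(x$catches$catch), "/", x$params$n_movers, "\n", sep = "")
  invisible(x)
}

#' Per-trap catches of a simulation
#'
#' @param x A `crw_sim`.
#' @param ... Unused.
#' @return Tibble with one row per trap: `trap_id`, `row`, `col`, `x`, `y`,
#'   `side`, `catch`.
#' @export
#' @method tidy crw_sim
tidy.crw_sim <- function(x, ...) x$catches

#' One-row simulation summary
#'
#' @param x A `crw_sim`.
#' @param ... Unused.
#' @return Tibble with `n_movers`, `n_captured`, `n_free`,
#'   `capture_fraction`, `csd_deg`, `n_steps`.
#' @export
#' @method glance crw_sim
glance.crw_sim <- function(x, ...) {
  cap <- sum(x$catches$catch)
  tibble::tibble(
    n_movers = x$params$n_movers, n_captured = cap,
    n_free = x$params$n_movers - cap,
    capture_fraction = cap / x$params$n_movers,
    csd_deg = x$params$csd_deg, n_steps = x$params$n_steps
  )
}

#' Serialize a simulation result to JSON
#'
#' @param sim A `crw_sim`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_sim_json <- function(sim, path) {
  stopifnot(inherits(sim, "crw_sim"))
  obj <- list(
    params = sim$params,
    catches = stats::setNames(as.list(sim$catches$catch), sim$catches$trap_id),
    free_positions = dplyr::filter(sim$movers, is.na(.data$captured_by))[, c("x", "y")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
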