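#' Sweep capture rate across c.s.d. values
#'
#' Runs `n_runs` independent simulations per c.s.d. value and records the
#' mean and standard error of the number of movers captured. This is the
#' experiment behind the capture-saturation curve at high target density
#' (centre release) and the interior optimum at low target density
#' (single distant trap).
#'
#' @param scenario A `trap_scenario`.
#' @param csd_values c.s.d. values to sweep, degrees (default 10-80 by 10).
#' @param n_runs Replicates per c.s.d. value.
#' @param n_movers,n_steps Walk parameters per run.
#' @param seed Master seed; each run gets a child stream.
#' @return A `capture_sweep`: tibble `runs` (`csd_deg`, `run`, `seed`,
#'   `captured`), tibble `summary` (`csd_deg`, `mean_captures`,
#'   `sem_captures`, `n_runs`), and a parameter echo.
#' @export
#' @examples
#' \donttest{
#' sw <- run_capture_sweep(scenario_center_release(),
#'                         csd_values = c(10, 40, 70), n_runs = 2,
#'                         n_movers = 100, n_steps = 500, seed = 1)
#' sw$summary
#' }
run_capture_sweep <- function(scenario,
                              csd_values = seq(10, 80, by = 10),
                              n_runs = 12, n_movers = 1000, n_steps = 2000,
                              seed = NULL) {
  stopifnot(inherits(scenario, "trap_scenario"), length(csd_values) >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)

  design <- tidyr::expand_grid(csd_deg = sort(unique(csd_values)),
                               run = seq_len(n_runs))
  design$seed <- spawn_seeds(seed, nrow(design))
  design$captured <- purrr::pmap_int(design, function(csd_deg, run, seed) {
    sim <- simulate_walkers(scenario, csd_deg, n_movers = n_movers,
                            n_steps = n_steps, seed = seed)
    sum(sim$catches$catch)
  })

  summary <- design |>
    dplyr::group_by(.data$csd_deg) |>
    dplyr::summarise(
      mean_captures = mean(.data$captured),
      sem_captures = stats::sd(.data$captured) / sqrt(dplyr::n()),
      n_runs = dplyr::n(), .groups = "drop")
  summary$sem_captures[is.na(summary$sem_captures)] <- 0

  structure(list(runs = design, summary = summary,
                 params = list(scenario = scenario$name,
                               n_movers = n_movers, n_steps = n_steps,
                               n_runs = n_runs, seed = seed)),
            class = "capture_sweep")
}

#' @export
print.capture_sweep <- function(x, ...) {
  cat("<capture_sweep> ", x$params$scenario, ": ",
      nrow(x$summary), " c.s.d. values x ", x$params$n_runs, " runs\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_capture_sweep
#' @param x A `capture_sweep`.
#' @param ... Unused.
#' @return `tidy()`: the per-c.s.d. summary tibble.
#' @export
#' @method tidy capture_sweep
tidy.capture_sweep <- function(x, ...) x$summary

#' Optimal c.s.d. of a capture sweep
#'
#' The optimum is the smallest tested c.s.d. whose mean capture is
#' statistically tied with the sweep maximum — within one pooled standard
#' error of it — which reads a saturating curve as "first value reaching
#' the plateau" while remaining well-defined for an interior peak.
#'
#' @param sweep A `capture_sweep` (>= 3 c.s.d. values) or its summary
#'   tibble.
#' @return One-row tibble: `optimal_csd`, `max_mean`, `pooled_sem`,
#'   `boundary` (`TRUE` when the optimum sits at the largest tested value)
#'   and `flat` (`TRUE`, with `optimal_csd = NA`, when the sweep range is
#'   below one pooled SEM: no detectable optimum).
#' @export
find_optimal_csd <- function(sweep) {
  s <- if (inherits(sweep, "capture_sweep")) sweep$summary else sweep
  stopifnot(all(c("csd_deg", "mean_captures", "sem_captures") %in% names(s)))
  if (nrow(s) < 3) stop("sweep needs >= 3 c.s.d. values", call. = FALSE)
  s <- dplyr::arrange(s, .data$csd_deg)
  pooled <- sqrt(mean(s$sem_captures^2))
  mx <- max(s$mean_captures)
  if (mx - min(s$mean_captures) < pooled) {
    return(tibble::tibble(optimal_csd = NA_real_, max_mean = mx,
                          pooled_sem = pooled, boundary = FALSE,
                          flat = TRUE))
  }
  tied <- s$csd_deg[s$mean_captures >= mx - pooled]
  opt <- min(tied)
  tibble::tibble(optimal_csd = opt, max_mean = mx, pooled_sem = pooled,
                 boundary = opt == max(s$csd_deg), flat = FALSE)
}

#' Target density of a scenario
#'
#' Area per trap under the scenario's reference area: the uniform seeding
#' rectangle for an arena scenario, and the grid bounding box for a
#' lattice — reported under both box conventions, the trap-centre
#' bounding box (`"tight"`) and the box expanded by half a spacing on each
#' side (`"cell"`, one full lattice cell per trap, the default).
#'
#' @param scenario A `trap_scenario`.
#' @param reference_density Optional comparison density, square units per
#'   target, for the fold change.
#' @param convention `"cell"` or `"tight"` (grids only).
#' @return One-row tibble: `area`, `n_traps`, `area_per_target`,
#'   `convention`, and `fold_change` when a reference is given.
#' @export
#' @examples
#' target_density(scenario_low_density(), reference_density = 300)
target_density <- function(scenario, reference_density = NULL,
                           convention = c("cell", "tight")) {
  stopifnot(inherits(scenario, "trap_scenario"))
  convention <- match.arg(convention)
  n <- nrow(scenario$traps)
  if (n == 0) stop("scenario has no traps", call. = FALSE)

  if (scenario$release$mode == "uniform") {
    rel <- scenario$release
    area <- (rel$xmax - rel$xmin) * (rel$ymax - rel$ymin)
    convention <- "arena"
  } else {
    w <- diff(range(scenario$traps$x))
    h <- diff(range(scenario$traps$y))
    if (convention == "cell") {
      # half a lattice spacing of margin on every side
      sp <- if (n > 1) min(dist(unique(cbind(scenario$traps$x, scenario$traps$y)))) else 0
      w <- w + sp
      h <- h + sp
    }
    area <- w * h
  }
  out <- tibble::tibble(area = area, n_traps = n,
                        area_per_target = area / n,
                        convention = convention)
  if (!is.null(reference_density)) {
    stopifnot(reference_density > 0)
    out$fold_change <- out$area_per_target / reference_density
  }
  out
}

#' Plot a capture sweep
#'
#' @param object A `capture_sweep`.
#' @param ... Unused.
#' @return A ggplot of mean capture (with SEM bars) against c.s.d.
#' @export
#' @method autoplot capture_sweep
autoplot.capture_sweep <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$csd_deg, .data$mean_captures)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_captures - .data$sem_captures,
      ymax = .data$mean_captures + .data$sem_captures), width = 1) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Circular standard deviation (degrees)",
                  y = "Mean capture",
                  title = paste("Capture sweep:", object$params$scenario)) +
    ggplot2::theme_minimal()
}
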