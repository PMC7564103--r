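#' Read field-style catch tables
#'
#' Expects a long CSV with one row per trap cell: columns `replicate_id`,
#' `row`, `col`, `catch`, `release_corner`, optionally `release_size` and
#' `label`. Every replicate must form a complete rows x cols grid of
#' non-negative integer counts with a valid release corner.
#'
#' @param path CSV file path (or anything `readr::read_csv()` accepts).
#' @return A list of `catch_table` objects, one per replicate; each is a
#'   list with `replicate_id`, `catches` (tibble `trap_id`, `row`, `col`,
#'   `catch`), `release_corner`, `release_size`, `label`.
#' @export
read_catch_tables <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("replicate_id", "row", "col", "catch", "release_corner")
  if (!all(need %in% names(d))) {
    stop("catch CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  purrr::map(split(d, d$replicate_id), validate_catch_table)
}

validate_catch_table <- function(d) {
  id <- d$replicate_id[1]
  bad <- d$catch < 0 | d$catch != floor(d$catch)
  if (any(bad)) {
    stop(sprintf("replicate %s: negative or non-integer count at cell (%d, %d)",
                 id, d$row[bad][1], d$col[bad][1]), call. = FALSE)
  }
  corner <- unique(d$release_corner)
  if (length(corner) != 1 || !corner %in% c("NW", "NE", "SW", "SE")) {
    stop(sprintf("replicate %s: invalid release corner", id), call. = FALSE)
  }
  nr <- max(d$row) + 1L
  nc <- max(d$col) + 1L
  want <- tidyr::expand_grid(row = 0:(nr - 1), col = 0:(nc - 1))
  got <- dplyr::distinct(d[, c("row", "col")])
  if (nrow(got) != nrow(d) || nrow(dplyr::anti_join(want, got,
                                                    by = c("row", "col"))) > 0) {
    miss <- dplyr::anti_join(want, got, by = c("row", "col"))
    cell <- if (nrow(miss) > 0) sprintf(" (%d, %d)", miss$row[1], miss$col[1]) else ""
    stop(sprintf("replicate %s: missing or duplicated cell%s", id, cell),
         call. = FALSE)
  }
  size <- if ("release_size" %in% names(d)) d$release_size[1] else NA_real_
  if (!is.na(size) && sum(d$catch) > size) {
    stop(sprintf("replicate %s: total catch exceeds release size", id),
         call. = FALSE)
  }
  structure(list(
    replicate_id = as.character(id),
    catches = tibble::tibble(
      trap_id = sprintf("r%dc%d", d$row, d$col),
      row = as.integer(d$row), col = as.integer(d$col),
      catch = as.integer(d$catch)),
    release_corner = corner,
    release_size = size,
    label = if ("label" %in% names(d)) as.character(d$label[1]) else NA_character_
  ), class = "catch_table")
}

#' @export
print.catch_table <- function(x, ...) {
  cat("<catch_table> replicate ", x$replicate_id, ": ",
      max(x$catches$row) + 1, "x", max(x$catches$col) + 1,
      " grid, corner ", x$release_corner, ", total catch ",
      sum(x$catches$catch), "\n", sep = "")
  invisible(x)
}

#' Rotate a catch table to the canonical release corner
#'
#' Field releases may happen at any of the four grid corners; analysis
#' uses a single canonical orientation (release at the NW corner, grid
#' index row 0 / col 0). Rotating the grid by the appropriate half or
#' quarter turn maps the release corner onto NW while permuting the cell
#' catches consistently. Idempotent: an NW table passes through unchanged.
#'
#' @param table A `catch_table`.
#' @return The same `catch_table` in canonical orientation.
#' @export
orient_to_release_corner <- function(table) {
  stopifnot(inherits(table, "catch_table"))
  if (table$release_corner == "NW") return(table)
  nr <- max(table$catches$row)
  nc <- max(table$catches$col)
  d <- table$catches
  flip_r <- table$release_corner %in% c("SW", "SE")
  flip_c <- table$release_corner %in% c("NE", "SE")
  d$row <- if (flip_r) nr - d$row else d$row
  d$col <- if (flip_c) nc - d$col else d$col
  d$trap_id <- sprintf("r%dc%d", d$row, d$col)
  table$catches <- dplyr::arrange(d, .data$row, .data$col)
  table$release_corner <- "NW"
  table
}

#' Analyze field catch tables against a standard curve
#'
#' Per replicate: orient to the canonical corner, label the edge traps,
#' aggregate the edge profile, fit the decay constant k, and invert k
#' through the standard curve into a c.s.d. estimate. Replicates whose
#' decay fit is impossible (fewer than three positive edge bins) are
#' excluded and reported.
#'
#' @param tables List of `catch_table` objects (from
#'   [read_catch_tables()] or [generate_field_fixture()]).
#' @param curve A `standard_curve`.
#' @param hist_breaks Histogram bin edges for the c.s.d. determinations,
#'   degrees (default 5-degree bins from 10 to 65).
#' @return A `field_summary`: per-replicate tibble `replicates`
#'   (`replicate_id`, `k`, `r_squared`, `csd_deg`, `extrapolated`),
#'   scalars `mean_k`, `sem_k`, `mean_csd`, `sem_csd`, histogram tibble
#'   `histogram`, and `unfittable` (excluded replicate ids).
#' @export
analyze_field <- function(tables, curve, hist_breaks = seq(10, 65, by = 5)) {
  stopifnot(length(tables) >= 1, inherits(curve, "standard_curve"))
  one <- function(tb) {
    tb <- orient_to_release_corner(tb)
    fit <- tryCatch(
      suppressWarnings(decay_from_catches(tb$catches, "NW")),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(replicate_id = tb$replicate_id, k = NA_real_,
                            r_squared = NA_real_, csd_deg = NA_real_,
                            extrapolated = NA))
    }
    inv <- invert_csd(curve, fit$k)
    tibble::tibble(replicate_id = tb$replicate_id, k = fit$k,
                   r_squared = fit$r_squared, csd_deg = inv$csd_deg,
                   extrapolated = inv$extrapolated)
  }
  reps <- purrr::map_dfr(tables, one)
  ok <- reps[!is.na(reps$k), ]
  if (nrow(ok) == 0) stop("no replicate could be fitted", call. = FALSE)
  n <- nrow(ok)
  sem <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else 0

  br <- hist_breaks
  if (any(ok$csd_deg < min(br)) || any(ok$csd_deg > max(br))) {
    br <- pretty(c(br, ok$csd_deg), n = length(br))
  }
  h <- graphics::hist(ok$csd_deg, breaks = br, plot = FALSE)

  structure(list(
    replicates = reps,
    n_replicates = n,
    mean_k = mean(ok$k), sem_k = sem(ok$k),
    mean_csd = mean(ok$csd_deg), sem_csd = sem(ok$csd_deg),
    csd_range = range(ok$csd_deg),
    histogram = tibble::tibble(bin_lo = utils::head(h$breaks, -1),
                               bin_hi = utils::tail(h$breaks, -1),
                               count = h$counts),
    unfittable = reps$replicate_id[is.na(reps$k)]
  ), class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf(paste0("<field_summary> %d replicate(s): k = %.3f +/- %.3f ",
                     "(S.E.M.), c.s.d. = %.1f +/- %.1f deg\n"),
              x$n_replicates, x$mean_k, x$sem_k, x$mean_csd, x$sem_csd))
  if (length(x$unfittable) > 0) {
    cat("  unfittable replicates: ", paste(x$unfittable, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname analyze_field
#' @param x A `field_summary`.
#' @param ... Unused.
#' @return `tidy()`: the per-replicate k / c.s.d. tibble.
#' @export
#' @method tidy field_summary
tidy.field_summary <- function(x, ...) x$replicates

#' @rdname analyze_field
#' @export
#' @method glance field_summary
glance.field_summary <- function(x, ...) {
  tibble::tibble(n_replicates = x$n_replicates,
                 mean_k = x$mean_k, sem_k = x$sem_k,
                 mean_csd = x$mean_csd, sem_csd = x$sem_csd,
                 csd_min = x$csd_range[1], csd_max = x$csd_range[2],
                 n_unfittable = length(x$unfittable))
}

#' Histogram of per-replicate c.s.d. determinations
#'
#' @param object A `field_summary`.
#' @param ... Unused.
#' @return A ggplot frequency histogram of the replicate c.s.d. values.
#' @export
#' @method autoplot field_summary
autoplot.field_summary <- function(object, ...) {
  ok <- object$replicates[!is.na(object$replicates$csd_deg), ]
  ggplot2::ggplot(ok, ggplot2::aes(.data$csd_deg)) +
    ggplot2::geom_histogram(breaks = c(object$histogram$bin_lo,
                                       max(object$histogram$bin_hi)),
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Circular standard deviation (degrees)",
                  y = "Replicates",
                  title = sprintf("c.s.d. determinations (mean %.1f deg)",
                                  object$mean_csd)) +
    ggplot2::theme_minimal()
}

#' Generate synthetic field-style catch tables
#'
#' Simulates mark-release-recapture replicates on the corner-release grid:
#' each replicate releases `release_size` movers at the corner release
#' point, walks them for `n_steps`, and records per-trap catches.
#' Optional binomial thinning of each trap's catch emulates an overall
#' recapture rate below 100%. Release corners cycle through all four
#' labels so the orientation path is exercised, mirroring field practice
#' of releasing at different corners.
#'
#' These are synthetic fixtures: they emulate the sampling design and the
#' multinomial catch noise of a field experiment, not orchard covariates
#' (weather, lure aging, trap saturation) or between-night behavioural
#' variation.
#'
#' @param true_csd True circular standard deviation of the simulated
#'   movers, degrees.
#' @param n_replicates Number of replicate tables.
#' @param release_size Movers released per replicate (default 800).
#' @param n_steps Steps per mover (default 400, matching the calibration
#'   run length so fixture and curve are consistent).
#' @param recapture_p Per-trap binomial thinning probability in [0, 1]
#'   (default 1: no thinning).
#' @param scenario Corner-release scenario.
#' @param seed Master seed; replicates draw child streams.
#' @return List of `catch_table` objects.
#' @export
#' @examples
#' \donttest{
#' tabs <- generate_field_fixture(37, n_replicates = 3, seed = 1)
#' tabs[[1]]
#' }
generate_field_fixture <- function(true_csd, n_replicates,
                                   release_size = 800, n_steps = 400,
                                   recapture_p = 1,
                                   scenario = scenario_corner_release(),
                                   seed = NULL) {
  stopifnot(n_replicates >= 1, release_size >= 1,
            recapture_p >= 0, recapture_p <= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  seeds <- spawn_seeds(seed, n_replicates)
  corners <- rep(c("NW", "NE", "SW", "SE"), length.out = n_replicates)
  nr <- max(scenario$traps$row)
  nc <- max(scenario$traps$col)

  purrr::map(seq_len(n_replicates), function(i) {
    sim <- simulate_walkers(scenario, true_csd, n_movers = release_size,
                            n_steps = n_steps, seed = seeds[i])
    d <- sim$catches
    if (recapture_p < 1) {
      d$catch <- with_local_seed(seeds[i] %% 1000000L + 7L,
                                 stats::rbinom(nrow(d), d$catch, recapture_p))
    }
    # express the canonical (NW-release) simulation in the labelled
    # corner's orientation; orient_to_release_corner() undoes this
    corner <- corners[i]
    flip_r <- corner %in% c("SW", "SE")
    flip_c <- corner %in% c("NE", "SE")
    d$row <- if (flip_r) nr - d$row else d$row
    d$col <- if (flip_c) nc - d$col else d$col
    d$trap_id <- sprintf("r%dc%d", d$row, d$col)
    structure(list(
      replicate_id = sprintf("sim%02d", i),
      catches = dplyr::arrange(d[, c("trap_id", "row", "col", "catch")],
                               .data$row, .data$col),
      release_corner = corner,
      release_size = release_size,
      label = sprintf("synthetic csd=%g", true_csd)
    ), class = "catch_table")
  })
}

#' Write catch tables to the long CSV schema
#'
#' @param tables List of `catch_table` objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_catch_tables <- function(tables, path) {
  d <- purrr::map_dfr(tables, function(tb) {
    dplyr::mutate(tb$catches[, c("row", "col", "catch")],
                  replicate_id = tb$replicate_id,
                  release_corner = tb$release_corner,
                  release_size = tb$release_size,
                  label = tb$label,
                  .before = 1)
  })
  readr::write_csv(d, path)
  invisible(path)
}
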