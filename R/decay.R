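#' Label edge traps by distance from the release corner
#'
#' After a corner release only the traps on the two grid edges adjacent to
#' the release corner are used: the corner trap itself is T1 and the i-th
#' trap along each adjacent edge belongs to index T(i+1), giving one trap
#' at index 1 and a symmetric pair at every later index. All other traps
#' are interior and excluded from the decay analysis.
#'
#' @param traps Trap tibble with `row`/`col` grid indices (a scenario's
#'   `$traps` or [tidy()] of one).
#' @param release_corner Which grid corner the release is outside of:
#'   `"NW"` (row 0, col 0 — the canonical corner), `"NE"`, `"SW"`, `"SE"`.
#' @return Tibble `trap_id`, `edge_index` (integer, `NA` for interior).
#' @export
#' @examples
#' lab <- label_edge_traps(scenario_corner_release()$traps)
#' table(lab$edge_index)
label_edge_traps <- function(traps, release_corner = "NW") {
  stopifnot(all(c("trap_id", "row", "col") %in% names(traps)))
  release_corner <- match.arg(release_corner, c("NW", "NE", "SW", "SE"))
  nr <- max(traps$row) + 1L
  nc <- max(traps$col) + 1L
  # grid indices of the release corner
  cr <- switch(release_corner, NW = 0L, NE = 0L, SW = nr - 1L, SE = nr - 1L)
  cc <- switch(release_corner, NW = 0L, SW = 0L, NE = nc - 1L, SE = nc - 1L)
  dr <- abs(traps$row - cr)
  dc <- abs(traps$col - cc)
  on_edge <- (dr == 0L) | (dc == 0L)
  idx <- ifelse(on_edge, pmax(dr, dc) + 1L, NA_integer_)
  tibble::tibble(trap_id = traps$trap_id, edge_index = as.integer(idx))
}

#' Aggregate catches into the edge-trap profile
#'
#' T1 keeps the corner trap's catch; each later index takes the arithmetic
#' mean of its two equidistant edge traps (the pairing the release-diagonal
#' symmetry justifies). Interior traps are dropped.
#'
#' @param catches Tibble with `trap_id` and `catch` (e.g. `tidy()` of a
#'   [simulate_walkers()] result).
#' @param labels Edge labels from [label_edge_traps()] on the same grid.
#' @return Tibble `edge_index`, `mean_catch`, `n_traps`, ordered by index.
#' @export
aggregate_edge_catches <- function(catches, labels) {
  stopifnot(all(c("trap_id", "catch") %in% names(catches)))
  missing <- setdiff(labels$trap_id, catches$trap_id)
  if (length(missing) > 0) {
    stop("catches missing trap(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dplyr::inner_join(labels, catches, by = "trap_id") |>
    dplyr::filter(!is.na(.data$edge_index)) |>
    dplyr::group_by(.data$edge_index) |>
    dplyr::summarise(mean_catch = mean(.data$catch),
                     n_traps = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$edge_index)
}

#' Fit the exponential decay constant of edge-trap catch
#'
#' Ordinary least squares of `ln(mean_catch)` on edge index over the bins
#' with positive catch: the slope is the decay constant k (per trap
#' interval; shifting the index origin leaves it unchanged). Zero-catch
#' bins are dropped with a warning rather than imputed, and at least three
#' positive bins are required for a fit. A nonlinear mode
#' (`method = "nls"`) fits `a * exp(k * index)` to the raw means directly
#' for sensitivity checks; both agree exactly on noise-free exponentials.
#'
#' @param profile Edge profile from [aggregate_edge_catches()] (columns
#'   `edge_index`, `mean_catch`).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return A `decay_fit` object with elements `k`, `intercept`,
#'   `r_squared`, `n_bins_used`, `profile`, `method`; see [tidy.decay_fit()].
#' @export
#' @examples
#' prof <- tibble::tibble(edge_index = 1:5, mean_catch = exp(-(1:5)))
#' fit_decay(prof)$k
fit_decay <- function(profile, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(all(c("edge_index", "mean_catch") %in% names(profile)))
  keep <- profile$mean_catch > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-catch bin(s) dropped from decay fit",
            call. = FALSE)
  }
  d <- profile[keep, ]
  if (nrow(d) < 3) {
    stop("decay fit needs >= 3 bins with positive catch (got ", nrow(d), ")",
         call. = FALSE)
  }
  if (method == "loglinear") {
    fit <- stats::lm(log(mean_catch) ~ edge_index, data = d)
    k <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  } else {
    start <- stats::coef(stats::lm(log(mean_catch) ~ edge_index, data = d))
    fit <- stats::nls(mean_catch ~ exp(b + k * edge_index), data = d,
                      start = list(b = start[[1]], k = start[[2]]),
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    k <- unname(stats::coef(fit)[["k"]])
    b <- unname(stats::coef(fit)[["b"]])
    r2 <- 1 - sum(stats::resid(fit)^2) /
      sum((d$mean_catch - mean(d$mean_catch))^2)
  }
  structure(list(k = k, intercept = b, r_squared = r2,
                 n_bins_used = nrow(d), profile = profile, method = method),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4f (r^2 = %.3f, %d bins, %s)\n",
              x$k, x$r_squared, x$n_bins_used, x$method))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
#' @method tidy decay_fit
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "k"),
                 estimate = c(x$intercept, x$k))
}

#' @rdname fit_decay
#' @export
#' @method glance decay_fit
glance.decay_fit <- function(x, ...) {
  tibble::tibble(k = x$k, intercept = x$intercept,
                 r_squared = x$r_squared, n_bins_used = x$n_bins_used,
                 method = x$method)
}

#' Decay constant straight from per-trap catches
#'
#' Convenience pipeline: label edge traps, build the profile, fit k.
#'
#' @param catches Per-trap catch tibble with `trap_id`, `row`, `col`,
#'   `catch`.
#' @param release_corner Release corner label (see [label_edge_traps()]).
#' @param ... Passed to [fit_decay()].
#' @return A `decay_fit`.
#' @export
decay_from_catches <- function(catches, release_corner = "NW", ...) {
  labels <- label_edge_traps(catches, release_corner)
  fit_decay(aggregate_edge_catches(catches, labels), ...)
}

#' Plot an edge-trap decay fit
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot: mean catch (log scale) against edge-trap index with
#'   the fitted exponential.
#' @export
#' @method autoplot decay_fit
autoplot.decay_fit <- function(object, ...) {
  d <- object$profile[object$profile$mean_catch > 0, ]
  line <- tibble::tibble(
    edge_index = seq(min(d$edge_index), max(d$edge_index), length.out = 50)
  )
  line$mean_catch <- exp(object$intercept + object$k * line$edge_index)
  ggplot2::ggplot(d, ggplot2::aes(.data$edge_index, .data$mean_catch)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Edge trap index (T1 nearest release)",
                  y = "Mean catch",
                  title = sprintf("Catch decay: k = %.3f", object$k)) +
    ggplot2::theme_minimal()
}
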