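#' Build the standard curve relating decay constant to c.s.d.
#'
#' For every c.s.d. value in `csd_grid`, runs `n_reps` independent
#' corner-release simulations, fits the edge-trap decay constant k of
#' each, and regresses all replicate k values on c.s.d. The relationship
#' is close to linear over the working range, so the fitted line serves
#' as a standard curve for translating a measured k into a c.s.d.
#' estimate via [invert_csd()].
#'
#' The default grid spans 15-50 degrees, bracketing both the postulated
#' optimal band (30-50 degrees) and the spread seen in field
#' determinations, with 10 replicates of 400 movers x 400 steps per value.
#'
#' @param csd_grid Calibration c.s.d. values, degrees, in (0, 90]; at
#'   least 4 distinct values.
#' @param n_reps Replicate simulations per c.s.d. (default 10, >= 2).
#' @param scenario Corner-release scenario (default
#'   [scenario_corner_release()]).
#' @param n_movers,n_steps Walk parameters per replicate (defaults 400 and
#'   400).
#' @param seed Master seed; every replicate draws its own child stream.
#' @return A `standard_curve`: slope `m` (k per degree), `intercept` `b`
#'   (k at 0 degrees), `r_squared` (linearity of mean k on c.s.d.),
#'   `r_squared_replicates` (same on all replicate points), `residual_sd`,
#'   replicate table
#'   `replicates` (`csd_deg`, `rep`, `seed`, `k`, `r_squared`),
#'   `valid_range`, and the coefficient covariance `vcov`.
#' @export
#' @examples
#' \donttest{
#' curve <- build_standard_curve(c(20, 30, 40, 50), n_reps = 3, seed = 1)
#' glance(curve)
#' }
build_standard_curve <- function(csd_grid = seq(15, 50, by = 5),
                                 n_reps = 10,
                                 scenario = scenario_corner_release(),
                                 n_movers = 400, n_steps = 400,
                                 seed = NULL) {
  csd_grid <- sort(unique(csd_grid))
  stopifnot(length(csd_grid) >= 4, all(csd_grid > 0), all(csd_grid <= 90),
            n_reps >= 2)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)

  design <- tidyr::expand_grid(csd_deg = csd_grid, rep = seq_len(n_reps))
  design$seed <- spawn_seeds(seed, nrow(design))
  labels <- label_edge_traps(scenario$traps)

  fit_one <- function(csd_deg, rep, seed) {
    sim <- simulate_walkers(scenario, csd_deg, n_movers = n_movers,
                            n_steps = n_steps, seed = seed)
    fit <- tryCatch(
      fit_decay(aggregate_edge_catches(sim$catches, labels)),
      error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(k = NA_real_, r_squared = NA_real_)
    } else {
      tibble::tibble(k = fit$k, r_squared = fit$r_squared)
    }
  }
  reps <- dplyr::bind_cols(design, purrr::pmap_dfr(design, fit_one))

  bad <- is.na(reps$k)
  if (any(bad)) {
    warning(sum(bad), " unfittable replicate(s) excluded from calibration",
            call. = FALSE)
  }
  if (mean(bad) > 0.2) {
    stop("more than 20% of calibration replicates were unfittable",
         call. = FALSE)
  }
  ok <- reps[!bad, ]

  # regression on all replicate points, retaining replicate variance
  fit <- stats::lm(k ~ csd_deg, data = ok)
  vc <- stats::vcov(fit)
  dimnames(vc) <- NULL
  # linearity diagnostic on the per-c.s.d. mean k values (the quantity the
  # standard curve displays); the replicate-point r^2 is also kept
  mk <- stats::aggregate(k ~ csd_deg, data = ok, FUN = mean)
  r2_means <- summary(stats::lm(k ~ csd_deg, data = mk))$r.squared
  structure(list(
    m = unname(stats::coef(fit)[2]),
    b = unname(stats::coef(fit)[1]),
    r_squared = r2_means,
    r_squared_replicates = summary(fit)$r.squared,
    residual_sd = summary(fit)$sigma,
    vcov = vc,
    replicates = reps,
    csd_grid = csd_grid,
    valid_range = range(csd_grid),
    params = list(n_reps = n_reps, scenario = scenario$name,
                  n_movers = n_movers, n_steps = n_steps, seed = seed)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> k = %.4f + %.5f * csd ",
                     "(r^2 = %.3f, %d replicates, csd %g-%g deg)\n"),
              x$b, x$m, x$r_squared, sum(!is.na(x$replicates$k)),
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @rdname build_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return `tidy()`: the replicate-level k table.
#' @export
#' @method tidy standard_curve
tidy.standard_curve <- function(x, ...) x$replicates

#' @rdname build_standard_curve
#' @export
#' @method glance standard_curve
glance.standard_curve <- function(x, ...) {
  tibble::tibble(m = x$m, b = x$b, r_squared = x$r_squared,
                 r_squared_replicates = x$r_squared_replicates,
                 residual_sd = x$residual_sd,
                 csd_min = x$valid_range[1], csd_max = x$valid_range[2],
                 n_replicates = sum(!is.na(x$replicates$k)))
}

#' Predicted k at a c.s.d. value
#'
#' @param object A `standard_curve`.
#' @param csd_deg c.s.d. values, degrees.
#' @param ... Unused.
#' @return Predicted decay constants `b + m * csd_deg`.
#' @export
predict.standard_curve <- function(object, csd_deg, ...) {
  object$b + object$m * csd_deg
}

#' Invert a measured decay constant into a c.s.d. estimate
#'
#' Point estimate `(k - b) / m`. The standard error combines, by
#' first-order (delta-method) propagation, the measurement error of k and
#' the sampling covariance of the curve coefficients; both components are
#' also reported separately.
#'
#' @param curve A `standard_curve`.
#' @param k Measured decay constant.
#' @param k_se Standard error of `k` (0 for an exact value).
#' @return One-row tibble: `csd_deg`, `se_deg` (combined), `se_meas_deg`,
#'   `se_curve_deg`, `extrapolated` (outside the calibrated range).
#' @export
#' @examples
#' \donttest{
#' curve <- build_standard_curve(c(20, 30, 40, 50), n_reps = 3, seed = 1)
#' invert_csd(curve, k = -0.99, k_se = 0.02)
#' }
invert_csd <- function(curve, k, k_se = 0) {
  stopifnot(inherits(curve, "standard_curve"), is.finite(k), k_se >= 0)
  if (abs(curve$m) < 1e-12) stop("curve slope is ~0; cannot invert",
                                 call. = FALSE)
  csd <- (k - curve$b) / curve$m
  # gradient of (k - b)/m w.r.t. (b, m)
  g <- c(-1 / curve$m, -(k - curve$b) / curve$m^2)
  var_curve <- drop(t(g) %*% curve$vcov %*% g)
  var_meas <- (k_se / curve$m)^2
  tibble::tibble(
    csd_deg = csd,
    se_deg = sqrt(var_curve + var_meas),
    se_meas_deg = sqrt(var_meas),
    se_curve_deg = sqrt(var_curve),
    extrapolated = csd < curve$valid_range[1] | csd > curve$valid_range[2]
  )
}

#' Persist a standard curve to JSON (and read it back)
#'
#' Stores coefficients, covariance, replicate k values and seeds so a
#' calibration can be reused across analyses bit-for-bit.
#'
#' @param curve A `standard_curve`.
#' @param path JSON file path.
#' @return `write_standard_curve()`: `path` invisibly;
#'   `read_standard_curve()`: the restored `standard_curve`.
#' @export
write_standard_curve <- function(curve, path) {
  stopifnot(inherits(curve, "standard_curve"))
  obj <- unclass(curve)
  obj$vcov <- as.vector(obj$vcov)  # 2x2, row-major-agnostic (symmetric)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standard_curve
#' @export
read_standard_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$vcov <- matrix(obj$vcov, 2, 2)
  obj$replicates <- tibble::as_tibble(obj$replicates)
  obj$valid_range <- as.numeric(obj$valid_range)
  structure(obj, class = "standard_curve")
}

#' Plot a standard curve
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot of replicate k values against c.s.d. with the fitted
#'   line.
#' @export
#' @method autoplot standard_curve
autoplot.standard_curve <- function(object, ...) {
  reps <- object$replicates[!is.na(object$replicates$k), ]
  ggplot2::ggplot(reps, ggplot2::aes(.data$csd_deg, .data$k)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$b, slope = object$m,
                         colour = "steelblue") +
    ggplot2::labs(x = "Circular standard deviation (degrees)",
                  y = "Decay constant k",
                  title = sprintf("Standard curve: k = %.3f %+.4f csd (r^2 = %.2f)",
                                  object$b, object$m, object$r_squared)) +
    ggplot2::theme_minimal()
}
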