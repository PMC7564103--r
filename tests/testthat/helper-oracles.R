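# Independent oracles used across tests. These deliberately re-derive
# results with different algorithms from the package internals.

# First trap hit along straight rays from (x0, y0): vectorised interval
# (slab) clipping per trap, all in R. Returns per-trap hit proportions.
oracle_ray_proportions <- function(scenario, n_rays, ray_len, seed) {
  set.seed(seed)
  theta <- stats::runif(n_rays, 0, 2 * pi)
  x0 <- scenario$release$x
  y0 <- scenario$release$y
  dx <- ray_len * cos(theta)
  dy <- ray_len * sin(theta)
  traps <- scenario$traps
  h <- traps$side / 2
  t_entry <- matrix(Inf, n_rays, nrow(traps))
  for (j in seq_len(nrow(traps))) {
    lo_x <- (traps$x[j] - h[j] - x0) / dx
    hi_x <- (traps$x[j] + h[j] - x0) / dx
    lo_y <- (traps$y[j] - h[j] - y0) / dy
    hi_y <- (traps$y[j] + h[j] - y0) / dy
    t1 <- pmax(pmin(lo_x, hi_x), pmin(lo_y, hi_y), 0)
    t2 <- pmin(pmax(lo_x, hi_x), pmax(lo_y, hi_y), 1)
    t_entry[, j] <- ifelse(t1 <= t2, t1, Inf)
  }
  first <- apply(t_entry, 1, function(r) {
    if (all(is.infinite(r))) 0L else which.min(r)
  })
  counts <- tabulate(first, nbins = nrow(traps))
  stats::setNames(counts / n_rays, traps$trap_id)
}

# point-in-square membership along a densely sampled segment
oracle_dense_segment_hit <- function(x0, y0, x1, y1, trap_x, trap_y, side,
                                     n_points = 1e4) {
  t <- seq(0, 1, length.out = n_points)
  px <- x0 + t * (x1 - x0)
  py <- y0 + t * (y1 - y0)
  any(abs(px - trap_x) <= side / 2 & abs(py - trap_y) <= side / 2)
}

# ordinary least squares by explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# hand-built standard_curve object with exact coefficients and no
# coefficient uncertainty (for algebraic inversion checks)
exact_curve <- function(m, b, valid_range = c(0, 90)) {
  structure(list(m = m, b = b, r_squared = 1, residual_sd = 0,
                 vcov = matrix(0, 2, 2), replicates = tibble::tibble(),
                 csd_grid = valid_range, valid_range = valid_range,
                 params = list()),
            class = "standard_curve")
}

# catch_table built from a 5x5 matrix of counts (row 1 = grid row 0)
table_from_matrix <- function(m, corner = "NW", id = "r1", release_size = NA) {
  g <- expand.grid(row = 0:(nrow(m) - 1), col = 0:(ncol(m) - 1))
  structure(list(
    replicate_id = id,
    catches = tibble::tibble(
      trap_id = sprintf("r%dc%d", g$row, g$col),
      row = as.integer(g$row), col = as.integer(g$col),
      catch = as.integer(m[cbind(g$row + 1, g$col + 1)])),
    release_corner = corner,
    release_size = release_size,
    label = NA_character_
  ), class = "catch_table")
}
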