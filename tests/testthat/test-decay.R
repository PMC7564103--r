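test_that("edge labelling gives T1 plus symmetric pairs", {
  sc <- scenario_corner_release()
  lab <- label_edge_traps(sc$traps)
  counts <- table(lab$edge_index)
  expect_equal(sum(!is.na(lab$edge_index)), 9)
  expect_equal(counts[["1"]], 1)
  expect_equal(as.integer(counts[c("2", "3", "4", "5")]), rep(2L, 4))
  expect_equal(sum(is.na(lab$edge_index)), 16)

  # smallest non-degenerate grid: T1 plus one pair
  g2 <- pathmeander:::grid_traps(2, 2, 15, 2)
  lab2 <- label_edge_traps(g2)
  expect_equal(sort(lab2$edge_index[!is.na(lab2$edge_index)]), c(1, 2, 2))
})

test_that("edge labelling follows the release corner", {
  sc <- scenario_corner_release()
  lab <- label_edge_traps(sc$traps, "SE")
  t1 <- lab$trap_id[which(lab$edge_index == 1)]
  expect_equal(t1, "r4c4")
  expect_error(label_edge_traps(sc$traps, "center"), "arg")
})

test_that("pair catches are averaged and missing traps rejected", {
  sc <- scenario_corner_release()
  lab <- label_edge_traps(sc$traps)
  catches <- dplyr::mutate(sc$traps, catch = 0)
  catches$catch[catches$trap_id == "r0c0"] <- 5
  catches$catch[catches$trap_id == "r0c1"] <- 10
  catches$catch[catches$trap_id == "r1c0"] <- 14
  prof <- aggregate_edge_catches(catches, lab)
  expect_equal(prof$mean_catch[prof$edge_index == 2], 12)
  expect_equal(prof$mean_catch[prof$edge_index == 1], 5)
  expect_error(aggregate_edge_catches(catches[-1, ], lab), "missing trap")
})

test_that("paired edge traps agree within counting noise on a diagonal release", {
  sc <- scenario_corner_release()
  sim <- simulate_walkers(sc, 30, n_movers = 2000, n_steps = 400, seed = 88)
  lab <- label_edge_traps(sc$traps)
  d <- dplyr::inner_join(sim$catches, lab, by = "trap_id") |>
    dplyr::filter(!is.na(edge_index), edge_index > 1) |>
    dplyr::group_by(edge_index) |>
    dplyr::summarise(diff = abs(diff(catch)), total = sum(catch))
  # pair difference behaves like binomial(total, 1/2) noise
  expect_true(all(d$diff <= 4 * sqrt(d$total + 1)))
})

test_that("exact exponential profiles are fitted exactly", {
  prof <- tibble::tibble(edge_index = 1:5, mean_catch = exp(-(1:5)))
  fit <- fit_decay(prof)
  expect_equal(fit$k, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- fit_decay(tibble::tibble(edge_index = 1:5,
                                   mean_catch = rep(100, 5)))
  expect_equal(flat$k, 0, tolerance = 1e-12)
  # nonlinear mode agrees on noise-free input
  expect_equal(fit_decay(prof, method = "nls")$k, -1, tolerance = 1e-6)
})

test_that("log-linear fit matches the normal-equations oracle", {
  set.seed(61)
  k_true <- -0.9
  prof <- tibble::tibble(
    edge_index = 1:5,
    mean_catch = exp(4 + k_true * (1:5) + rnorm(5, 0, 0.1)))
  fit <- fit_decay(prof)
  ora <- oracle_ols(prof$edge_index, log(prof$mean_catch))
  expect_equal(fit$k, ora[2], tolerance = 1e-10)
  expect_equal(fit$intercept, ora[1], tolerance = 1e-10)
})

test_that("k is invariant to catch scaling and index shifts", {
  set.seed(62)
  prof <- tibble::tibble(edge_index = 1:5,
                         mean_catch = exp(3 - 0.7 * (1:5) + rnorm(5, 0, 0.2)))
  f0 <- fit_decay(prof)
  scaled <- dplyr::mutate(prof, mean_catch = mean_catch * 37.5)
  expect_equal(fit_decay(scaled)$k, f0$k, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fit_decay(scaled)$intercept, f0$intercept)))
  shifted <- dplyr::mutate(prof, edge_index = edge_index - 1)
  expect_equal(fit_decay(shifted)$k, f0$k, tolerance = 1e-12)
})

test_that("degenerate profiles are unfittable and zero bins are dropped", {
  zeros <- tibble::tibble(edge_index = 1:5, mean_catch = rep(0, 5))
  expect_error(suppressWarnings(fit_decay(zeros)), ">= 3 bins")
  some <- tibble::tibble(edge_index = 1:5, mean_catch = c(8, 4, 2, 0, 0))
  expect_warning(fit <- fit_decay(some), "zero-catch")
  expect_equal(fit$n_bins_used, 3)
  expect_equal(fit$k, -log(2), tolerance = 1e-12)
})

test_that("simulated corner release at c.s.d. 30 reproduces the expected decay", {
  sc <- scenario_corner_release()
  ks <- vapply(1:10, function(i) {
    sim <- simulate_walkers(sc, 30, n_movers = 400, n_steps = 400,
                            seed = 9000 + i)
    suppressWarnings(decay_from_catches(sim$catches)$k)
  }, numeric(1))
  expect_lt(abs(mean(ks) - (-0.91)), 0.1)
})
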