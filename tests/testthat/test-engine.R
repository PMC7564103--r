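test_that("zero steps means no movement and no catch", {
  sc <- scenario_corner_release()
  sim <- simulate_walkers(sc, 30, n_movers = 17, n_steps = 0, seed = 1)
  expect_true(all(sim$catches$catch == 0))
  expect_equal(sim$movers$x, rep(sc$release$x, 17))
  expect_equal(sim$movers$y, rep(sc$release$y, 17))
})

test_that("movers are conserved in every run", {
  sc_list <- list(scenario_corner_release(), scenario_center_release(),
                  scenario_low_density())
  set.seed(77)
  for (sc in sc_list) {
    for (csd in c(0, 12, 47)) {
      n <- sample(20:80, 1)
      sim <- simulate_walkers(sc, csd, n_movers = n,
                              n_steps = sample(50:300, 1),
                              seed = sample.int(1e6, 1))
      expect_equal(sum(sim$catches$catch) +
                     sum(is.na(sim$movers$captured_by)), n)
    }
  }
})

test_that("identical seed and parameters reproduce the run exactly", {
  sc <- scenario_low_density()
  a <- simulate_walkers(sc, 35, n_movers = 60, n_steps = 200, seed = 123)
  b <- simulate_walkers(sc, 35, n_movers = 60, n_steps = 200, seed = 123)
  expect_identical(a$catches, b$catches)
  expect_identical(a$movers, b$movers)
  c <- simulate_walkers(sc, 35, n_movers = 60, n_steps = 200, seed = 124)
  expect_false(identical(a$movers, c$movers))
})

test_that("captured movers rest on or inside their trap square", {
  sc <- scenario_corner_release()
  sim <- simulate_walkers(sc, 40, n_movers = 300, n_steps = 300, seed = 5)
  caught <- dplyr::filter(sim$movers, !is.na(captured_by))
  expect_gt(nrow(caught), 0)
  d <- dplyr::inner_join(caught, sc$traps,
                         by = c(captured_by = "trap_id"),
                         suffix = c("", "_trap"))
  expect_true(all(abs(d$x - d$x_trap) <= 1 + 1e-9))
  expect_true(all(abs(d$y - d$y_trap) <= 1 + 1e-9))
  expect_true(all(d$capture_step >= 1 & d$capture_step <= 300))
})

test_that("straight walkers match the independent ray-casting oracle", {
  sc <- scenario_corner_release()
  n_rays <- 1e5
  n_movers <- 2e4
  p_oracle <- oracle_ray_proportions(sc, n_rays, ray_len = 200, seed = 42)
  sim <- simulate_walkers(sc, 0, n_movers = n_movers, n_steps = 200,
                          seed = 314)
  p_sim <- setNames(sim$catches$catch / n_movers, sim$catches$trap_id)
  p_sim <- p_sim[names(p_oracle)]
  pool <- (p_oracle * n_rays + p_sim * n_movers) / (n_rays + n_movers)
  se <- sqrt(pool * (1 - pool) * (1 / n_rays + 1 / n_movers))
  expect_true(all(abs(p_sim - p_oracle) <= pmax(3 * se, 1e-12)))
})

test_that("release inside a trap is a geometry error", {
  sc <- scenario_low_density()
  sc$release <- list(mode = "point", x = 500, y = 300)
  expect_error(simulate_walkers(sc, 30, 10, 10, seed = 1), "inside a trap")
})

test_that("endpoint capture mode misses corner clips that segment mode catches", {
  sc <- scenario_corner_release()
  seg <- simulate_walkers(sc, 30, n_movers = 2000, n_steps = 150, seed = 21)
  end <- simulate_walkers(sc, 30, n_movers = 2000, n_steps = 150, seed = 21,
                          capture_mode = "endpoint")
  expect_gte(sum(seg$catches$catch), sum(end$catches$catch))
})
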