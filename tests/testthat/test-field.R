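test_that("catch-table CSV round-trips and validates", {
  tabs <- generate_field_fixture(30, n_replicates = 2, release_size = 200,
                                 n_steps = 150, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_catch_tables(tabs, path)
  back <- read_catch_tables(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$catches$catch, tabs[[1]]$catches$catch)
  expect_equal(back[[2]]$release_corner, tabs[[2]]$release_corner)
})

test_that("malformed tables are rejected with a cell-level message", {
  tabs <- generate_field_fixture(30, n_replicates = 1, release_size = 100,
                                 n_steps = 100, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")

  d <- readr::read_csv(write_catch_tables(tabs, path), show_col_types = FALSE)
  readr::write_csv(d[-5, ], path)
  expect_error(read_catch_tables(path), "missing or duplicated cell")

  d2 <- d; d2$catch[3] <- -1
  readr::write_csv(d2, path)
  expect_error(read_catch_tables(path), "negative")

  d3 <- d; d3$release_corner <- "XX"
  readr::write_csv(d3, path)
  expect_error(read_catch_tables(path), "corner")

  d4 <- d; d4$release_size <- 1
  readr::write_csv(d4, path)
  expect_error(read_catch_tables(path), "exceeds release size")
})

test_that("orientation maps any release corner onto the canonical grid", {
  m <- matrix(seq_len(25), 5, 5, byrow = TRUE)  # asymmetric counts

  nw <- table_from_matrix(m, "NW")
  expect_identical(orient_to_release_corner(nw)$catches, nw$catches)

  # SE release = 180-degree rotation of the canonical grid
  m_se <- m[5:1, 5:1]
  se <- orient_to_release_corner(table_from_matrix(m_se, "SE"))
  expect_equal(se$release_corner, "NW")
  got <- matrix(0, 5, 5)
  got[cbind(se$catches$row + 1, se$catches$col + 1)] <- se$catches$catch
  expect_equal(got, m)
  # corner cell value preserved
  expect_equal(se$catches$catch[se$catches$row == 0 & se$catches$col == 0],
               m_se[5, 5])

  # NE and SW releases are single-axis flips
  ne <- orient_to_release_corner(table_from_matrix(m[, 5:1], "NE"))
  sw <- orient_to_release_corner(table_from_matrix(m[5:1, ], "SW"))
  for (tb in list(ne, sw)) {
    got <- matrix(0, 5, 5)
    got[cbind(tb$catches$row + 1, tb$catches$col + 1)] <- tb$catches$catch
    expect_equal(got, m)
  }

  # idempotent
  twice <- orient_to_release_corner(orient_to_release_corner(se))
  expect_identical(twice$catches, se$catches)
})

test_that("the fitted k is invariant to the recorded release corner", {
  set.seed(12)
  m <- matrix(rpois(25, 10) + 1, 5, 5)
  k_ref <- decay_from_catches(
    orient_to_release_corner(table_from_matrix(m, "NW"))$catches)$k
  rotations <- list(NE = m[, 5:1], SW = m[5:1, ], SE = m[5:1, 5:1])
  for (corner in names(rotations)) {
    tb <- table_from_matrix(rotations[[corner]], corner)
    k <- decay_from_catches(orient_to_release_corner(tb)$catches)$k
    expect_equal(k, k_ref, tolerance = 1e-12)
  }
})

test_that("exact exponential replicates give exact summaries", {
  m <- matrix(0L, 5, 5)
  m[1, ] <- c(81L, 27L, 9L, 3L, 1L)   # row 0 edge
  m[, 1] <- c(81L, 27L, 9L, 3L, 1L)   # col 0 edge
  tb <- table_from_matrix(m, "NW")
  curve <- exact_curve(m = -0.03, b = 0)
  fs <- suppressWarnings(analyze_field(list(tb), curve))
  expect_equal(fs$mean_k, -log(3), tolerance = 1e-12)
  expect_equal(fs$sem_k, 0)
  expect_equal(fs$mean_csd, -log(3) / -0.03, tolerance = 1e-12)

  # duplicated replicates: zero spread
  fs2 <- suppressWarnings(analyze_field(list(tb, tb), curve))
  expect_equal(fs2$sem_k, 0)
  expect_equal(fs2$n_replicates, 2)
})

test_that("fixtures have the field design shape and conservation", {
  tabs <- generate_field_fixture(37, n_replicates = 8, release_size = 300,
                                 n_steps = 200, seed = 99)
  expect_length(tabs, 8)
  for (tb in tabs) {
    expect_equal(nrow(tb$catches), 25)
    expect_lte(sum(tb$catches$catch), 300)
  }
  expect_setequal(unique(vapply(tabs, `[[`, "", "release_corner")),
                  c("NW", "NE", "SW", "SE"))
})

test_that("full thinning produces empty, unfittable tables", {
  tabs <- generate_field_fixture(30, n_replicates = 2, release_size = 100,
                                 n_steps = 100, recapture_p = 0, seed = 3)
  expect_true(all(vapply(tabs, function(tb) sum(tb$catches$catch), 1) == 0))
  curve <- exact_curve(m = -0.03, b = 0)
  expect_error(suppressWarnings(analyze_field(tabs, curve)), "no replicate")
})

test_that("field analysis recovers the generating c.s.d.", {
  curve <- build_standard_curve(c(25, 30, 35, 40, 45), n_reps = 4,
                                seed = 555)
  tabs <- generate_field_fixture(37, n_replicates = 12, release_size = 800,
                                 n_steps = 400, seed = 556)
  fs <- suppressWarnings(analyze_field(tabs, curve))
  expect_lt(abs(fs$mean_csd - 37), 4)
  expect_equal(fs$n_replicates, 12)
  expect_equal(sum(fs$histogram$count), 12)
})
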