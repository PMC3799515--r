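# Case-side adaptive-bandwidth kernel ratio estimation, checked cell-for-cell
# against a literal double-loop oracle and its own mass/bandwidth identities.

test_that("bandwidth is zero when the threshold is met in the case's own cell", {
  g <- grid_geometry(10, 10)
  births <- tibble::tibble(cell_row = c(3, 3, 3, 8), cell_col = c(4, 4, 4, 8))
  expect_equal(adaptive_bandwidth(c(3, 4), births, 1, g), 0)
  expect_equal(adaptive_bandwidth(c(3, 4), births, 3, g), 0)
  expect_gt(adaptive_bandwidth(c(3, 4), births, 4, g), 0)
  one_cell <- tibble::tibble(cell_row = rep(5, 7), cell_col = rep(5, 7))
  expect_equal(adaptive_bandwidth(c(5, 5), one_cell, 7, g), 0)
  expect_error(adaptive_bandwidth(c(5, 5), one_cell, 8, g), "fewer than")
})

test_that("adaptive bandwidth equals the brute-force sorted-distance oracle", {
  g <- grid_geometry(50, 50, cell_size = 100)
  births <- random_births(100, g, seed = 31)
  cc <- cell_centers(g)
  for (trial in 1:10) {
    case <- c(births$cell_row[trial], births$cell_col[trial])
    x0 <- cc$x[cc$cell_row == case[1] & cc$cell_col == case[2]][1]
    y0 <- cc$y[cc$cell_row == case[1] & cc$cell_col == case[2]][1]
    bc <- cell_centers(g, births$cell_row, births$cell_col)
    d <- sort(sqrt((bc$x - x0)^2 + (bc$y - y0)^2))
    for (t_enc in c(1, 10, 50, 100)) {
      expect_equal(adaptive_bandwidth(case, births, t_enc, g), d[t_enc])
    }
  }
})

test_that("bandwidth is minimal and monotone in the enclosure threshold", {
  g <- grid_geometry(30, 30, cell_size = 100)
  births <- random_births(150, g, seed = 13)
  bc <- cell_centers(g, births$cell_row, births$cell_col)
  for (trial in c(1, 40, 90)) {
    case <- c(births$cell_row[trial], births$cell_col[trial])
    x0 <- bc$x[trial]; y0 <- bc$y[trial]
    d_all <- sqrt((bc$x - x0)^2 + (bc$y - y0)^2)
    r_prev <- 0
    for (t_enc in c(1, 5, 25, 75, 150)) {
      r <- adaptive_bandwidth(case, births, t_enc, g)
      expect_gte(sum(d_all <= r), t_enc)                   # encloses enough
      if (r > 0) expect_lt(sum(d_all <= r - 1e-9), t_enc)  # minimally so
      expect_gte(r, r_prev)                                # monotone in T
      r_prev <- r
    }
  }
})

test_that("a stratum with no cases yields an all-zero surface", {
  g <- grid_geometry(15, 15)
  births <- random_births(50, g, n_cases = 0, seed = 5)
  births$stratum <- "s"
  surf <- stratum_intensity(births, 10, g)
  expect_true(all(surf$values == 0))
})

test_that("a fully co-located support gives the forced 1/n cell value", {
  g <- grid_geometry(9, 9)
  t_enc <- 6
  births <- tibble::tibble(cell_row = rep(4, t_enc), cell_col = rep(7, t_enc),
                           is_case = c(TRUE, rep(FALSE, t_enc - 1)),
                           stratum = "s")
  surf <- stratum_intensity(births, t_enc, g)
  expect_equal(surf$values[4, 7], 1 / t_enc)
  expect_equal(sum(surf$values), 1 / t_enc)
})

test_that("surfaces match the double-loop oracle cell-for-cell", {
  g <- grid_geometry(20, 20, cell_size = 100)
  births <- random_births(120, g, n_cases = 6, seed = 21)
  births$stratum <- "s"
  for (kern in c("epanechnikov", "quartic", "uniform")) {
    surf <- stratum_intensity(births, 15, g, kernel = kern)
    oracle <- oracle_intensity(births, 15, g, kernel = kern)
    expect_lt(max(abs(surf$values - oracle)), 1e-12)
  }
})

test_that("oracle equivalence holds at the 50x50 / 200-birth scale", {
  g <- grid_geometry(50, 50, cell_size = 100)
  births <- random_births(200, g, n_cases = 8, seed = 42)
  births$stratum <- "s"
  surf <- stratum_intensity(births, 25, g)
  oracle <- oracle_intensity(births, 25, g)
  expect_lt(max(abs(surf$values - oracle)), 1e-12)
})

test_that("every case distributes exactly one unit of mass over its support", {
  g <- grid_geometry(25, 25, cell_size = 100)
  for (seed in c(3, 17)) {
    births <- random_births(180, g, n_cases = 1, seed = seed)
    births$stratum <- "s"
    surf <- stratum_intensity(births, 20, g)
    cohort <- cohort_cell_counts(births, g)
    # birth-weighted mass: sum_j contribution_j * births_j = 1 per case
    expect_equal(sum(surf$values * cohort$values), 1, tolerance = 1e-12)
  }
  # and additively for several cases
  births <- random_births(180, g, n_cases = 7, seed = 23)
  births$stratum <- "s"
  surf <- stratum_intensity(births, 20, g)
  cohort <- cohort_cell_counts(births, g)
  expect_equal(sum(surf$values * cohort$values), 7, tolerance = 1e-12)
})

test_that("combining a single stratum divides by its statewide rate", {
  g <- grid_geometry(5, 5)
  vals <- matrix(runif(25), 5, 5)
  co <- matrix(rpois(25, 3), 5, 5)
  surf <- rcmc_raster(vals, g, "s")
  rates <- tibble::tibble(stratum = "s", case_total = 2L,
                          cohort_total = 100L, rate = 0.02)
  comb <- combine_strata(list(s = surf), rates, list(s = co))
  sup <- co > 0
  expect_equal(comb$values[sup], vals[sup] / 0.02)
  expect_true(all(comb$values[!sup] == 0))
  expect_identical(attr(comb, "support"), sup)
})

test_that("strata exactly at their statewide rates combine to 1", {
  g <- grid_geometry(4, 4)
  rates <- tibble::tibble(stratum = c("a", "b"), case_total = c(1L, 1L),
                          cohort_total = c(50L, 20L), rate = c(0.02, 0.05))
  surfs <- list(a = rcmc_raster(matrix(0.02, 4, 4), g, "a"),
                b = rcmc_raster(matrix(0.05, 4, 4), g, "b"))
  co <- list(a = matrix(3, 4, 4), b = matrix(1, 4, 4))
  comb <- combine_strata(surfs, rates, co)
  expect_equal(comb$values, matrix(1, 4, 4))
})

test_that("two-stratum combination matches the hand-computed formula", {
  g <- grid_geometry(5, 5)
  set.seed(77)
  i_a <- matrix(runif(25, 0, 0.1), 5, 5)
  i_b <- matrix(runif(25, 0, 0.1), 5, 5)
  co_a <- matrix(rpois(25, 2), 5, 5)
  co_b <- matrix(rpois(25, 1), 5, 5)
  rates <- tibble::tibble(stratum = c("a", "b"), case_total = c(1L, 1L),
                          cohort_total = c(10L, 10L), rate = c(0.0145, 0.0194))
  comb <- combine_strata(
    list(a = rcmc_raster(i_a, g, "a"), b = rcmc_raster(i_b, g, "b")),
    rates, list(a = co_a, b = co_b)
  )
  # independent elementwise spreadsheet computation
  expected <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    tot <- co_a[r, c] + co_b[r, c]
    if (tot > 0) {
      expected[r, c] <- (co_a[r, c] / tot) * i_a[r, c] / 0.0145 +
        (co_b[r, c] / tot) * i_b[r, c] / 0.0194
    }
  }
  expect_equal(comb$values, expected, tolerance = 1e-12)
})

test_that("mismatched grids are rejected", {
  a <- rcmc_raster(matrix(0, 4, 4), grid_geometry(4, 4), "a")
  b <- rcmc_raster(matrix(0, 5, 5), grid_geometry(5, 5), "b")
  rates <- tibble::tibble(stratum = c("a", "b"), case_total = c(1L, 1L),
                          cohort_total = c(10L, 10L), rate = c(0.1, 0.1))
  expect_error(
    combine_strata(list(a = a, b = b), rates,
                   list(a = matrix(1, 4, 4), b = matrix(1, 5, 5))),
    "mismatched"
  )
})

test_that("bandwidths above max_bandwidth are clamped with a warning", {
  g <- grid_geometry(20, 20, cell_size = 100)
  births <- random_births(60, g, n_cases = 3, seed = 9)
  births$stratum <- "s"
  expect_warning(
    surf <- stratum_intensity(births, 50, g, max_bandwidth = 150),
    "clamped"
  )
  expect_true(all(is.finite(surf$values)))
})
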