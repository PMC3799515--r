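# Null-scenario generation, rank p-values, uncertainty summaries, hot spots.

make_p <- function(vals, g = grid_geometry(nrow(vals), ncol(vals))) {
  rcmc_raster(vals, g, "p")
}

test_that("simulate_null keeps stratum totals but frees unit totals", {
  pts <- tibble::tibble(
    record_id = 1:6,
    unit_id = c("A", "A", "A", "B", "B", "B"),
    stratum = "s",
    cell_row = 1L, cell_col = 1:6,
    is_case = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  # trivial boundaries
  set.seed(1)
  none <- simulate_null(pts, c(s = 0L))
  expect_equal(sum(none$is_case), 0)
  all6 <- simulate_null(pts, c(s = 6L))
  expect_true(all(all6$is_case))
  expect_error(simulate_null(pts, c(s = 7L)), "exceed")
  # exhaustive sweep: all C(6,2) = 15 case sets occur, including sets that
  # concentrate both cases in one unit (unit totals are NOT preserved)
  keys <- character(3000)
  for (s in 1:3000) {
    set.seed(s)
    f <- simulate_null(pts, c(s = 2L))$is_case
    keys[s] <- paste(which(f), collapse = "-")
  }
  counts <- table(keys)
  expect_equal(length(counts), 15)
  expect_true("1-2" %in% names(counts))  # both cases in unit A
  expect_true("4-5" %in% names(counts))  # both cases in unit B
  gof <- chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("locations are untouched by null reselection", {
  pts <- tibble::tibble(record_id = 1:10, unit_id = "A", stratum = "s",
                        cell_row = rep(1:2, 5), cell_col = rep(1:5, 2),
                        is_case = rep(c(TRUE, FALSE), 5))
  set.seed(2)
  nul <- simulate_null(pts)
  expect_identical(nul$cell_row, pts$cell_row)
  expect_identical(nul$cell_col, pts$cell_col)
  expect_equal(sum(nul$is_case), sum(pts$is_case))
})

test_that("the rank rule gives p = 0.02 for the second highest of 100", {
  g <- grid_geometry(1, 1)
  obs <- make_p(matrix(5), g)
  nulls <- c(list(make_p(matrix(7), g)),
             lapply(runif(98, 0, 4), function(v) make_p(matrix(v), g)))
  p <- pvalue_surface(obs, nulls)
  expect_equal(p$values[1, 1], 0.02)
})

test_that("rank p-value boundaries and granularity", {
  g <- grid_geometry(1, 1)
  obs <- make_p(matrix(10), g)
  nulls <- lapply(1:19, function(v) make_p(matrix(v / 100), g))
  expect_equal(pvalue_surface(obs, nulls)$values[1, 1], 1 / 20)  # beats all
  low <- make_p(matrix(0), g)
  expect_equal(pvalue_surface(low, nulls)$values[1, 1], 1)       # beaten by all
  tied <- make_p(matrix(0.05), g)  # ties count against the observed
  expect_equal(pvalue_surface(tied, nulls)$values[1, 1], 16 / 20)
  # granularity: every p is a multiple of 1/(M+1)
  set.seed(8)
  g2 <- grid_geometry(6, 6)
  obs2 <- make_p(matrix(runif(36), 6, 6), g2)
  nulls2 <- lapply(1:7, function(i) make_p(matrix(runif(36), 6, 6), g2))
  p2 <- pvalue_surface(obs2, nulls2)
  expect_true(all(abs(p2$values * 8 - round(p2$values * 8)) < 1e-12))
  expect_true(all(p2$values > 0 & p2$values <= 1))
})

test_that("unsupported cells propagate as NA through p and summaries", {
  g <- grid_geometry(2, 2)
  obs <- make_p(matrix(c(1, 0, 0, 0), 2, 2), g)
  attr(obs, "support") <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  nulls <- lapply(1:9, function(i) make_p(matrix(0, 2, 2), g))
  p <- pvalue_surface(obs, nulls)
  expect_true(is.na(p$values[2, 2]))
  expect_equal(p$values[1, 1], 0.1)
})

test_that("grid mismatch between observed and nulls is rejected", {
  obs <- make_p(matrix(0, 2, 2))
  expect_error(pvalue_surface(obs, list(make_p(matrix(0, 3, 3)))), "mismatched")
})

test_that("uncertainty summary reproduces hand-computed mean and SD", {
  g <- grid_geometry(1, 1)
  s1 <- make_p(matrix(0.02), g)
  s2 <- make_p(matrix(0.04), g)
  u <- uncertainty_summary(list(s1, s2))
  expect_equal(u$mean_p$values[1, 1], 0.03)
  expect_equal(u$sd_p$values[1, 1], sqrt((0.01^2 + 0.01^2) / 1))
  expect_error(uncertainty_summary(list(s1)), "K >= 2")
  # identical surfaces: sd exactly 0, mean the common value
  u2 <- uncertainty_summary(list(s1, s1, s1))
  expect_equal(u2$sd_p$values[1, 1], 0)
  expect_equal(u2$mean_p$values[1, 1], 0.02)
})

test_that("mean p stays within (0, 1] and respects NA support counts", {
  g <- grid_geometry(2, 1)
  a <- make_p(matrix(c(0.5, NA), 2, 1), g)
  b <- make_p(matrix(c(0.7, NA), 2, 1), g)
  u <- uncertainty_summary(list(a, b))
  expect_equal(u$mean_p$values[1, 1], 0.6)
  expect_true(is.na(u$mean_p$values[2, 1]))
  expect_true(u$mean_p$values[1, 1] > 0 && u$mean_p$values[1, 1] <= 1)
})

test_that("the hot-spot rule is mean + 2 SD strictly below alpha", {
  g <- grid_geometry(1, 3)
  mean_p <- make_p(matrix(c(0.05, 0.05, 0.04), 1, 3), g)
  sd_p <- make_p(matrix(c(0.02, 0.03, 0.03), 1, 3), g)
  u <- structure(list(mean_p = mean_p, sd_p = sd_p, n_iterations = 2),
                 class = "rcmc_uncertainty")
  m <- hotspot_mask(u, alpha = 0.1)
  expect_equal(as.vector(m$values), c(1, 0, 0))  # 0.09 < 0.1; 0.11 no; 0.10 no (strict)
  expect_error(hotspot_mask(u, alpha = 0), "alpha")
})

test_that("hot-spot masks are monotone in alpha", {
  g <- grid_geometry(4, 4)
  set.seed(12)
  u <- uncertainty_summary(lapply(1:5, function(i) {
    make_p(matrix(runif(16, 0.01, 0.6), 4, 4), g)
  }))
  m1 <- hotspot_mask(u, 0.05)$values == 1
  m2 <- hotspot_mask(u, 0.2)$values == 1
  m3 <- hotspot_mask(u, 1)$values == 1
  expect_true(all(m2[m1]))   # mask(0.05) subset of mask(0.2)
  expect_true(all(m3[m2]))
  # alpha = 1 with finite sd < (1-mean)/2 marks; at least the subset relation holds
})
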