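# Shared fixtures, built in code. Cached within a test run so the heavier
# synthetic studies are generated once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# a small two-stratum study on a 30x30 grid, ~1,700 cohort births
small_study <- function() {
  cached("small_study", function() {
    simulate_study(
      n_units = 5, grid = grid_geometry(30, 30, cell_size = 100),
      strata = c("15-39", "40-49"),
      totals = c("15-39" = 30000, "40-49" = 4000),
      stratum_rates = c("15-39" = 0.0145, "40-49" = 0.0194),
      births_per_capita = 0.05, n_blobs = 4, seed = 7
    )
  })
}

# a single-unit map whose only unit spans a 1 x 2 grid (two cells)
two_cell_unit <- function() {
  cached("two_cell_unit", function() {
    make_geography(1, grid_geometry(1, 2, cell_size = 100), seed = 1)
  })
}

# independent double-loop KRE oracle: literal transcription of the estimator
# definition, no spatial shortcuts. births: tibble(cell_row, cell_col,
# is_case); returns the stratum intensity surface as a matrix.
oracle_intensity <- function(births, threshold, grid, kernel = "epanechnikov") {
  kern <- switch(kernel,
    epanechnikov = function(u) 1 - u^2,
    quartic = function(u) (1 - u^2)^2,
    uniform = function(u) rep(1, length(u))
  )
  ctr <- function(row, col) {
    c(grid$origin_x + (col - 0.5) * grid$cell_size,
      grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size)
  }
  surf <- matrix(0, grid$n_rows, grid$n_cols)
  cases <- births[births$is_case, ]
  for (ci in seq_len(nrow(cases))) {
    p0 <- ctr(cases$cell_row[ci], cases$cell_col[ci])
    d_b <- numeric(nrow(births))
    for (bi in seq_len(nrow(births))) {
      pb <- ctr(births$cell_row[bi], births$cell_col[bi])
      d_b[bi] <- sqrt(sum((p0 - pb)^2))
    }
    r <- sort(d_b)[threshold]
    if (r == 0) {
      n_self <- sum(births$cell_row == cases$cell_row[ci] &
                      births$cell_col == cases$cell_col[ci])
      surf[cases$cell_row[ci], cases$cell_col[ci]] <-
        surf[cases$cell_row[ci], cases$cell_col[ci]] + 1 / n_self
      next
    }
    w <- sum(kern(d_b[d_b <= r] / r))
    for (row in seq_len(grid$n_rows)) {
      for (col in seq_len(grid$n_cols)) {
        pj <- ctr(row, col)
        d <- sqrt(sum((p0 - pj)^2))
        if (d <= r) surf[row, col] <- surf[row, col] + kern(d / r) / w
      }
    }
  }
  surf
}

# scatter n births over a grid under one seed; m of them flagged as cases
random_births <- function(n, grid, n_cases = 0, seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(
    cell_row = sample.int(grid$n_rows, n, replace = TRUE),
    cell_col = sample.int(grid$n_cols, n, replace = TRUE),
    is_case = FALSE
  )
  if (n_cases > 0) out$is_case[sample.int(n, n_cases)] <- TRUE
  out
}
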