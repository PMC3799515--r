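# Monte Carlo significance: null case sets are drawn by simple random
# sampling from all cohort births of a stratum study-wide (town totals free
# to vary), the observed combined surface is ranked per cell among the null
# surfaces, and repetition over disaggregation iterations yields mean-p,
# SD-p and hot-spot maps that carry the aggregation-induced uncertainty.

#' Reassign case flags under the null hypothesis
#'
#' Null scenario generator: the per-stratum statewide case totals are kept,
#' but the cases are re-picked by simple random sampling without replacement
#' from all cohort births of that stratum, unconstrained by unit — so a null
#' draw can concentrate cases in any town. Locations are untouched. Uses the
#' current R random stream.
#'
#' @param points Birth-point tibble from [disaggregate()].
#' @param cases_per_stratum Named integer vector of case totals per stratum;
#'   defaults to the observed totals in `points`.
#' @return `points` with `is_case` reassigned.
#' @export
simulate_null <- function(points, cases_per_stratum = NULL) {
  if (is.null(cases_per_stratum)) {
    tot <- points |>
      group_by(.data$stratum) |>
      summarise(n = sum(.data$is_case), .groups = "drop")
    cases_per_stratum <- setNames(as.integer(tot$n), tot$stratum)
  }
  flags <- rep(FALSE, nrow(points))
  for (s in names(cases_per_stratum)) {
    idx <- which(points$stratum == s)
    m <- cases_per_stratum[[s]]
    if (m > length(idx)) {
      abort(sprintf("Stratum '%s': %d cases exceed the cohort total %d.",
                    s, m, length(idx)))
    }
    if (m > 0) flags[idx[sample.int(length(idx), m)]] <- TRUE
  }
  points$is_case <- flags
  points
}

#' Monte Carlo rank p-value surface
#'
#' Per cell, the observed intensity is ranked among `M` null-simulation
#' intensities: `p = (1 + #nulls >= observed) / (M + 1)`. Ties count against
#' the observed (conservative). An observed value that is the second highest
#' among the 100 values formed by 99 nulls plus itself gets p = 0.02. Cells
#' without cohort support (per the `support` attribute of the observed
#' surface) are set to `NA`.
#'
#' @param observed Combined `rcmc_raster` from [combine_strata()].
#' @param nulls List of `M >= 1` null combined surfaces on the same grid.
#' @return An `rcmc_raster` of p-values in (0, 1], with the `support`
#'   attribute carried through and an `n_null` attribute.
#' @export
pvalue_surface <- function(observed, nulls) {
  M <- length(nulls)
  if (M < 1) abort("Need at least one null surface.")
  for (nu in nulls) {
    if (!grid_equal(nu$grid, observed$grid)) abort("Null surface on a mismatched grid.")
  }
  count_ge <- matrix(0L, observed$grid$n_rows, observed$grid$n_cols)
  for (nu in nulls) count_ge <- count_ge + (nu$values >= observed$values)
  p <- (1 + count_ge) / (M + 1)
  support <- attr(observed, "support")
  if (!is.null(support)) p[!support] <- NA_real_
  out <- rcmc_raster(p, observed$grid, "p")
  attr(out, "support") <- support
  attr(out, "n_null") <- M
  out
}

#' Summarize p-value surfaces across disaggregation iterations
#'
#' Per cell, the arithmetic mean and the sample standard deviation
#' (denominator K - 1) of the K per-iteration p-values. A cell supported in
#' fewer than 2 iterations is `NA` in both maps. The SD map is the spatial
#' uncertainty induced purely by the unknown within-unit locations.
#'
#' @param p_surfaces List of `K >= 2` p-value surfaces on one grid.
#' @return An `rcmc_uncertainty` object: `mean_p` and `sd_p` rasters,
#'   `n_iterations`, and a per-cell count of supporting iterations.
#' @export
uncertainty_summary <- function(p_surfaces) {
  K <- length(p_surfaces)
  if (K < 2) abort("Need K >= 2 p-value surfaces (the SD is undefined otherwise).")
  grid <- p_surfaces[[1]]$grid
  for (ps in p_surfaces) {
    if (!grid_equal(ps$grid, grid)) abort("P-value surfaces on mismatched grids.")
  }
  n_cells <- grid$n_rows * grid$n_cols
  arr <- matrix(
    unlist(lapply(p_surfaces, function(ps) as.vector(ps$values))),
    nrow = n_cells, ncol = K
  )
  n_ok <- rowSums(!is.na(arr))
  mean_v <- rowMeans(arr, na.rm = TRUE)
  sd_v <- apply(arr, 1, sd, na.rm = TRUE)
  mean_v[n_ok < 2] <- NA_real_
  sd_v[n_ok < 2] <- NA_real_
  structure(
    list(
      mean_p = rcmc_raster(matrix(mean_v, grid$n_rows, grid$n_cols), grid, "mean_p"),
      sd_p = rcmc_raster(matrix(sd_v, grid$n_rows, grid$n_cols), grid, "sd_p"),
      n_support = matrix(n_ok, grid$n_rows, grid$n_cols),
      n_iterations = K
    ),
    class = "rcmc_uncertainty"
  )
}

#' @export
print.rcmc_uncertainty <- function(x, ...) {
  ok <- is.finite(x$mean_p$values)
  cat(sprintf(
    "<rcmc_uncertainty> K = %d iterations; %d supported cells; mean p range [%g, %g]\n",
    x$n_iterations, sum(ok),
    if (any(ok)) min(x$mean_p$values[ok]) else NA,
    if (any(ok)) max(x$mean_p$values[ok]) else NA
  ))
  invisible(x)
}

#' Hot-spot mask robust to aggregation uncertainty
#'
#' A cell is marked when its mean p-value plus two standard deviations is
#' still (strictly) below `alpha`: significant despite the disaggregation
#' uncertainty. Unsupported cells are `NA`.
#'
#' @param summary An [uncertainty_summary()] result.
#' @param alpha Significance level in (0, 1]; default 0.1.
#' @return An `rcmc_raster` of 1/0/NA with an `alpha` attribute.
#' @export
hotspot_mask <- function(summary, alpha = 0.1) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  m <- (summary$mean_p$values + 2 * summary$sd_p$values) < alpha
  out <- rcmc_raster(m + 0, summary$mean_p$grid, "hotspot")
  attr(out, "alpha") <- alpha
  out
}
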