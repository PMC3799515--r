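#' Full RCMC disease-mapping pipeline
#'
#' Runs the complete procedure: for each of `K` disaggregation iterations,
#' (1) place all cohort births and select cases by restricted and controlled
#' Monte Carlo, (2) build per-stratum case-side adaptive-bandwidth intensity
#' surfaces and combine them by indirect standardization, (3) run `M` null
#' simulations on that iteration's locations (cases re-picked study-wide at
#' fixed per-stratum totals) and convert the observed surface's per-cell rank
#' to a p-value; then average the `K` p-value maps into mean-p and SD-p maps
#' and mark hot spots where `mean_p + 2 * sd_p < alpha`.
#'
#' Defaults follow the original study design: `K = 50` disaggregations,
#' `M = 99` null simulations, `alpha = 0.1`, enclosure thresholds equal to
#' the rounded reciprocal of each stratum's statewide rate. Null simulations
#' are nested per iteration (re-drawn on that iteration's locations), and all
#' randomness derives from `master_seed`, so a rerun is bit-identical.
#'
#' @param aggregates Aggregate tibble (`unit_id`, `stratum`, `cohort_count`,
#'   `case_count`).
#' @param backgrounds Named list of per-stratum background `rcmc_raster`s.
#' @param unit_map An `rcmc_unit_map`.
#' @param K Number of disaggregation iterations (`>= 2`).
#' @param M Number of null simulations per iteration (`>= 1`).
#' @param alpha Hot-spot significance level.
#' @param kernel Kernel shape (see [stratum_intensity()]).
#' @param thresholds Optional named integer vector of per-stratum enclosure
#'   thresholds; defaults to [kernel_threshold()] of each stratum rate.
#' @param max_bandwidth Optional bandwidth cap in map units.
#' @param master_seed Master seed for the whole run.
#' @param uniform_fallback Passed to [disaggregate()].
#' @param keep_p Keep the K per-iteration p-value surfaces (default TRUE).
#' @param verbose Print per-iteration progress lines.
#' @return An `rcmc_result` list: `mean_p`, `sd_p`, `hotspots`, `summary`,
#'   `p_surfaces` (if kept), `rates`, `thresholds`, and the configuration.
#' @examples
#' \donttest{
#' study <- simulate_study(
#'   n_units = 4, grid = grid_geometry(25, 25, cell_size = 100),
#'   strata = "young", totals = c(young = 20000),
#'   stratum_rates = c(young = 0.015), births_per_capita = 0.05, seed = 2
#' )
#' res <- rcmc_pipeline(study$aggregates, study$backgrounds, study$unit_map,
#'                      K = 3, M = 19, master_seed = 9)
#' glance(res)
#' }
#' @export
rcmc_pipeline <- function(aggregates, backgrounds, unit_map,
                          K = 50, M = 99, alpha = 0.1,
                          kernel = "epanechnikov", thresholds = NULL,
                          max_bandwidth = NULL, master_seed = 1L,
                          uniform_fallback = FALSE, keep_p = TRUE,
                          verbose = FALSE) {
  if (K < 2) abort("`K` must be >= 2 (the SD over iterations is undefined).")
  if (M < 1) abort("`M` must be >= 1.")
  rates <- compute_stratum_rates(aggregates)
  strata <- rates$stratum
  if (is.null(thresholds)) {
    thresholds <- setNames(
      vapply(rates$rate, function(r) if (r > 0) kernel_threshold(r) else 1L,
             integer(1)),
      strata
    )
  }
  grid <- unit_map$grid
  p_surfaces <- vector("list", K)

  for (k in seq_len(K)) {
    pts <- disaggregate(aggregates, backgrounds, unit_map,
                        iteration_index = k, master_seed = master_seed,
                        uniform_fallback = uniform_fallback)
    by_stratum <- split(pts, pts$stratum)

    caches <- list()
    cohorts <- list()
    obs_counts <- list()
    case_totals <- integer(0)
    for (s in strata) {
      sp <- by_stratum[[s]]
      caches[[s]] <- kre_cache(sp, thresholds[[s]], grid, kernel, max_bandwidth)
      cohorts[[s]] <- cohort_cell_counts(sp, grid)
      obs_counts[[s]] <- case_counts_from_flags(caches[[s]], sp, sp$is_case)
      case_totals[s] <- sum(sp$is_case)
    }
    combine1 <- function(counts_by_stratum) {
      surfs <- lapply(strata, function(s) {
        rcmc_raster(surface_from_case_counts(caches[[s]], counts_by_stratum[[s]]),
                    grid, s)
      })
      names(surfs) <- strata
      combine_strata(surfs, rates, cohorts)
    }
    observed <- combine1(obs_counts)

    set.seed(derive_seed(master_seed, k, 7919))
    nulls <- vector("list", M)
    for (m in seq_len(M)) {
      null_counts <- lapply(strata, function(s) {
        sp <- by_stratum[[s]]
        flags <- rep(FALSE, nrow(sp))
        if (case_totals[s] > 0) {
          flags[sample.int(nrow(sp), case_totals[s])] <- TRUE
        }
        case_counts_from_flags(caches[[s]], sp, flags)
      })
      names(null_counts) <- strata
      nulls[[m]] <- combine1(null_counts)
    }
    p_surfaces[[k]] <- pvalue_surface(observed, nulls)
    if (verbose) {
      inform(sprintf("iteration %d/%d: %d cases, %d null simulations done",
                     k, K, sum(case_totals), M))
    }
  }

  summ <- uncertainty_summary(p_surfaces)
  mask <- hotspot_mask(summ, alpha)
  structure(
    list(
      mean_p = summ$mean_p, sd_p = summ$sd_p, hotspots = mask,
      summary = summ,
      p_surfaces = if (keep_p) p_surfaces else NULL,
      rates = rates, thresholds = thresholds,
      config = list(K = K, M = M, alpha = alpha, kernel = kernel,
                    max_bandwidth = max_bandwidth, master_seed = master_seed)
    ),
    class = "rcmc_result"
  )
}

#' @export
print.rcmc_result <- function(x, ...) {
  ok <- is.finite(x$mean_p$values)
  cat(sprintf(
    "<rcmc_result> K = %d, M = %d, alpha = %g | %d supported cells | %d hot-spot cells\n",
    x$config$K, x$config$M, x$config$alpha, sum(ok),
    sum(x$hotspots$values == 1, na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy a pipeline result into a cell-level tibble
#'
#' @param x An `rcmc_result`.
#' @param ... Unused.
#' @return A tibble with one row per supported cell: coordinates, `mean_p`,
#'   `sd_p`, `hotspot`.
#' @export
tidy.rcmc_result <- function(x, ...) {
  out <- as_tibble(x$mean_p) |> rename(mean_p = "value")
  out$sd_p <- as.vector(x$sd_p$values)
  out$hotspot <- as.vector(x$hotspots$values) == 1
  out[is.finite(out$mean_p), ]
}

#' One-row summary of a pipeline run
#'
#' @param x An `rcmc_result`.
#' @param ... Unused.
#' @return A one-row tibble: configuration, supported-cell count, hot-spot
#'   cell count and fraction.
#' @export
glance.rcmc_result <- function(x, ...) {
  ok <- is.finite(x$mean_p$values)
  n_hot <- sum(x$hotspots$values == 1, na.rm = TRUE)
  tibble(
    K = x$config$K, M = x$config$M, alpha = x$config$alpha,
    kernel = x$config$kernel, n_supported = sum(ok), n_hotspot = n_hot,
    frac_hotspot = if (sum(ok)) n_hot / sum(ok) else NA_real_
  )
}

#' @export
autoplot.rcmc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$mean_p)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = df[df$hotspot, ], ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, shape = 15, size = 0.8, colour = "red"
    ) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(direction = -1, na.value = "grey90") +
    ggplot2::labs(fill = "mean p", x = "easting", y = "northing",
                  title = "Mean p-value with hot spots (red)")
}
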