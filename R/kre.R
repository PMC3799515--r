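# Case-side adaptive-bandwidth kernel ratio estimation (KRE). Around every
# case a kernel grows until it encloses the number of cohort births that
# supports one expected case (the rounded reciprocal of the stratum rate);
# the case then spreads one unit of case mass over its support, giving each
# grid cell a local cases-per-cohort-birth intensity. Distances are Euclidean
# between cell centers, with no edge correction at the study-area boundary.

kernel_function <- function(shape = c("epanechnikov", "quartic", "uniform")) {
  shape <- match.arg(shape)
  switch(shape,
    epanechnikov = function(u) 1 - u^2,
    quartic = function(u) (1 - u^2)^2,
    uniform = function(u) rep(1, length(u))
  )
}

# smallest radius enclosing >= T births given distances d and per-cell counts n
bandwidth_from_dists <- function(d, n, threshold) {
  ord <- order(d)
  cum <- cumsum(n[ord])
  k <- which(cum >= threshold)[1]
  if (is.na(k)) return(NA_real_)
  d[ord][k]
}

#' Adaptive bandwidth for one case location
#'
#' The kernel radius is the center-to-center distance to the `threshold`-th
#' nearest cohort birth of the stratum — equivalently the smallest radius
#' enclosing at least `threshold` births. The case's own cohort record counts
#' toward the enclosure (it emerges from a support that includes itself), so
#' with `threshold = 1`, or with all births co-located in one cell, the
#' bandwidth is 0.
#'
#' @param case_cell Length-2 integer vector `c(cell_row, cell_col)`.
#' @param births Tibble of all cohort birth records of the stratum
#'   (`cell_row`, `cell_col`; one row per birth).
#' @param threshold Number of births to enclose (`>= 1`).
#' @param grid A [grid_geometry()].
#' @return Bandwidth in map units.
#' @export
adaptive_bandwidth <- function(case_cell, births, threshold, grid) {
  if (threshold < 1) abort("`threshold` must be >= 1.")
  if (nrow(births) < threshold) {
    abort(sprintf("Stratum has %d cohort births, fewer than the threshold %d.",
                  nrow(births), threshold))
  }
  occ <- births |> count(.data$cell_row, .data$cell_col, name = "n")
  cc <- cell_centers(grid, occ$cell_row, occ$cell_col)
  c0 <- cell_centers(grid, case_cell[1], case_cell[2])
  d <- sqrt((cc$x - c0$x)^2 + (cc$y - c0$y)^2)
  bandwidth_from_dists(d, occ$n, threshold)
}

# Contribution field of a single case sitting in cell (row0, col0).
# occ_*: plain vectors over occupied cohort cells (hot path: no tibbles).
# Returns list(r, idx (linear cell indices), val (per-case contribution)).
kre_field <- function(row0, col0, occ_row, occ_col, occ_n, occ_x, occ_y,
                      threshold, grid, kern, max_bandwidth = NULL) {
  cs <- grid$cell_size
  x0 <- grid$origin_x + (col0 - 0.5) * cs
  y0 <- grid$origin_y + (grid$n_rows - row0 + 0.5) * cs
  d_occ <- sqrt((occ_x - x0)^2 + (occ_y - y0)^2)
  r <- bandwidth_from_dists(d_occ, occ_n, threshold)
  clamped <- FALSE
  if (!is.null(max_bandwidth) && r > max_bandwidth) {
    r <- max_bandwidth
    clamped <- TRUE
  }
  n_rows <- grid$n_rows
  if (r == 0) {
    self_n <- occ_n[occ_row == row0 & occ_col == col0]
    return(list(r = 0, clamped = clamped,
                idx = row0 + (col0 - 1L) * n_rows, val = 1 / self_n))
  }
  keep <- d_occ <= r
  w_support <- sum(occ_n[keep] * kern(d_occ[keep] / r))
  # window of grid cells possibly within r
  span <- ceiling(r / cs)
  rows <- max(1L, row0 - span):min(grid$n_rows, row0 + span)
  cols <- max(1L, col0 - span):min(grid$n_cols, col0 + span)
  wr <- rep(rows, times = length(cols))
  wc <- rep(cols, each = length(rows))
  dx <- (wc - col0) * cs
  dy <- (wr - row0) * cs
  d_j <- sqrt(dx * dx + dy * dy)
  inside <- d_j <= r
  list(
    r = r, clamped = clamped,
    idx = wr[inside] + (wc[inside] - 1L) * n_rows,
    val = kern(d_j[inside] / r) / w_support
  )
}

# Precompute the per-case contribution field for every cohort-occupied cell of
# one stratum. Any simulated case configuration on these cohort locations is
# then a weighted sum of cached fields, which is what makes the nested null
# simulations cheap.
kre_cache <- function(births, threshold, grid,
                      kernel = "epanechnikov", max_bandwidth = NULL) {
  if (nrow(births) < threshold) {
    abort(sprintf("Stratum has %d cohort births, fewer than the threshold %d.",
                  nrow(births), threshold))
  }
  kern <- kernel_function(kernel)
  occ <- births |> count(.data$cell_row, .data$cell_col, name = "n")
  cc <- cell_centers(grid, occ$cell_row, occ$cell_col)
  occ$x <- cc$x
  occ$y <- cc$y
  occ_row <- occ$cell_row; occ_col <- occ$cell_col; occ_n <- occ$n
  occ_x <- occ$x; occ_y <- occ$y
  fields <- vector("list", nrow(occ))
  n_clamped <- 0L
  for (i in seq_len(nrow(occ))) {
    f <- kre_field(occ_row[i], occ_col[i], occ_row, occ_col, occ_n,
                   occ_x, occ_y, threshold, grid, kern, max_bandwidth)
    if (f$clamped) n_clamped <- n_clamped + 1L
    fields[[i]] <- f
  }
  if (n_clamped > 0) {
    warn(sprintf("%d adaptive bandwidth(s) exceeded max_bandwidth and were clamped.",
                 n_clamped))
  }
  # map linear cell index -> occupied-cell index, for fast case tabulation
  occ_of_cell <- integer(grid$n_rows * grid$n_cols)
  occ_lin <- occ$cell_row + (occ$cell_col - 1L) * grid$n_rows
  occ_of_cell[occ_lin] <- seq_len(nrow(occ))
  list(occ = occ, fields = fields, occ_of_cell = occ_of_cell, grid = grid)
}

# Sum cached fields weighted by the number of cases per occupied cell.
surface_from_case_counts <- function(cache, case_counts) {
  vals <- numeric(cache$grid$n_rows * cache$grid$n_cols)
  hit <- which(case_counts > 0)
  for (i in hit) {
    f <- cache$fields[[i]]
    vals[f$idx] <- vals[f$idx] + case_counts[i] * f$val
  }
  matrix(vals, cache$grid$n_rows, cache$grid$n_cols)
}

# per-occupied-cell case counts for a set of flagged records
case_counts_from_flags <- function(cache, births, flags) {
  lin <- births$cell_row[flags] + (births$cell_col[flags] - 1L) * cache$grid$n_rows
  tabulate(cache$occ_of_cell[lin], nbins = nrow(cache$occ))
}

#' Case-side adaptive-bandwidth intensity surface for one stratum
#'
#' For each case i with bandwidth r_i (distance to the `threshold`-th nearest
#' cohort birth), the kernel-weighted cohort support is
#' `W_i = sum over births b within r_i of K(d(i,b)/r_i)`, always positive
#' because the case's own record contributes `K(0)`. The case adds
#' `K(d(i,j)/r_i) / W_i` to every grid cell j within r_i; the surface is the
#' sum over cases, a local cases-per-cohort-birth intensity. When r_i = 0
#' (all support co-located with the case) the case adds `1/n` to its own cell
#' only, where n is the number of cohort births in that cell. Each case
#' distributes exactly one unit of case mass over its support: summing its
#' contribution times the per-cell cohort count gives 1.
#'
#' @param points Birth-point tibble (one stratum: `cell_row`, `cell_col`,
#'   `is_case`).
#' @param threshold Enclosure threshold for this stratum (see
#'   [kernel_threshold()]).
#' @param grid A [grid_geometry()]; defaults to the `grid` attribute of
#'   `points`.
#' @param kernel Kernel shape: `"epanechnikov"` (default), `"quartic"` or
#'   `"uniform"`. All are nonincreasing in distance and zero beyond the
#'   bandwidth.
#' @param max_bandwidth Optional cap in map units; larger adaptive bandwidths
#'   are clamped with a warning.
#' @return An `rcmc_raster` intensity surface.
#' @export
stratum_intensity <- function(points, threshold, grid = NULL,
                              kernel = "epanechnikov", max_bandwidth = NULL) {
  grid <- grid %||% attr(points, "grid")
  if (is.null(grid)) abort("Supply `grid` (or points carrying a grid attribute).")
  if (length(unique(points$stratum)) > 1) {
    abort("`points` must be restricted to a single stratum.")
  }
  label <- if (nrow(points)) points$stratum[1] else ""
  cases <- points[points$is_case, ]
  if (nrow(cases) == 0) {
    return(rcmc_raster(matrix(0, grid$n_rows, grid$n_cols), grid, label))
  }
  cache <- kre_cache(points, threshold, grid, kernel, max_bandwidth)
  cnt <- case_counts_from_flags(cache, points, points$is_case)
  rcmc_raster(surface_from_case_counts(cache, cnt), grid, label)
}

#' Combine stratum intensity surfaces by indirect standardization
#'
#' Each stratum's intensity is expressed relative to its overall (statewide)
#' rate and the strata are averaged with local cohort weights:
#' `combined_j = sum_s w_js * (I_js / rate_s)` with
#' `w_js = cohort_js / sum_s' cohort_js'`. Where no stratum has local cohort
#' the value is 0 and the cell is flagged unsupported (excluded from p-value
#' maps and hot-spot masks downstream). Under the null the combined surface
#' has expectation 1 wherever data exist.
#'
#' @param surfaces Named list of per-stratum `rcmc_raster` intensity surfaces.
#' @param rates Output of [compute_stratum_rates()] (or a named rate vector).
#' @param cohort_counts Named list of per-stratum cohort cell-count rasters
#'   (see [cohort_cell_counts()]); raw counts by default in the pipeline.
#' @return An `rcmc_raster` labelled `"combined"`, with a logical `support`
#'   attribute marking cells with positive local cohort.
#' @export
combine_strata <- function(surfaces, rates, cohort_counts) {
  strata <- names(surfaces)
  if (is.data.frame(rates)) {
    rates <- setNames(rates$rate, rates$stratum)
  }
  if (anyNA(rates[strata])) abort("`rates` must cover every stratum in `surfaces`.")
  grid <- surfaces[[1]]$grid
  for (s in strata) {
    if (!grid_equal(surfaces[[s]]$grid, grid)) abort("Surfaces are on mismatched grids.")
    cg <- cohort_counts[[s]]
    if (inherits(cg, "rcmc_raster") && !grid_equal(cg$grid, grid)) {
      abort("Cohort-count rasters are on mismatched grids.")
    }
  }
  num <- matrix(0, grid$n_rows, grid$n_cols)
  den <- matrix(0, grid$n_rows, grid$n_cols)
  for (s in strata) {
    co <- if (inherits(cohort_counts[[s]], "rcmc_raster")) {
      cohort_counts[[s]]$values
    } else cohort_counts[[s]]
    num <- num + co * surfaces[[s]]$values / rates[s]
    den <- den + co
  }
  vals <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  out <- rcmc_raster(vals, grid, "combined")
  attr(out, "support") <- den > 0
  out
}

#' Per-cell cohort counts for one stratum
#'
#' @param points Birth-point tibble restricted to one stratum.
#' @param grid A [grid_geometry()]; defaults to the points' grid attribute.
#' @return An `rcmc_raster` of cohort birth counts per cell.
#' @export
cohort_cell_counts <- function(points, grid = NULL) {
  grid <- grid %||% attr(points, "grid")
  if (is.null(grid)) abort("Supply `grid` (or points carrying a grid attribute).")
  lin <- points$cell_row + (points$cell_col - 1L) * grid$n_rows
  counts <- tabulate(lin, nbins = grid$n_rows * grid$n_cols)
  rcmc_raster(matrix(as.double(counts), grid$n_rows, grid$n_cols), grid, "cohort")
}
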