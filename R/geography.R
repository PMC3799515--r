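# Synthetic study areas: an irregular partition of a rectangular extent into
# town-like units, settlement-clustered background population rasters, and
# per-unit aggregate cohort/case counts. These emulate the statistical
# structure the disaggregation method assumes (aggregate counts by areal unit,
# a spatially heterogeneous at-risk background) so the whole pipeline can be
# exercised without any confidential registry data.

# ---- polygon helpers ---------------------------------------------------------

# Sutherland-Hodgman clip of a convex polygon (n x 2 matrix, open ring) by the
# half-plane a*x + b*y <= c.
clip_halfplane <- function(poly, a, b, c, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- a * poly[, 1] + b * poly[, 2] - c
  keep_in <- val <= tol
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (keep_in[i]) out <- rbind(out, p)
    if (xor(keep_in[i], keep_in[j])) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

# Voronoi cell of seed i among all seeds, clipped to the rectangular extent.
voronoi_cell <- function(i, sx, sy, ext) {
  poly <- cbind(
    c(ext["xmin"], ext["xmax"], ext["xmax"], ext["xmin"]),
    c(ext["ymin"], ext["ymin"], ext["ymax"], ext["ymax"])
  )
  for (j in seq_along(sx)) {
    if (j == i) next
    # closer-to-seed-i half-plane: 2(sj - si) . p <= |sj|^2 - |si|^2
    poly <- clip_halfplane(
      poly,
      2 * (sx[j] - sx[i]), 2 * (sy[j] - sy[i]),
      sx[j]^2 + sy[j]^2 - sx[i]^2 - sy[i]^2
    )
    if (nrow(poly) == 0) break
  }
  poly
}

# ---- unit map ---------------------------------------------------------------

new_unit_map <- function(units, assignment, grid) {
  structure(
    list(units = units, assignment = assignment, grid = grid),
    class = "rcmc_unit_map"
  )
}

#' @export
print.rcmc_unit_map <- function(x, ...) {
  cat(sprintf(
    "<rcmc_unit_map> %d units on a %d x %d grid; %d assigned cells\n",
    nrow(x$units), x$grid$n_rows, x$grid$n_cols, sum(!is.na(x$assignment))
  ))
  invisible(x)
}

#' Cell-to-unit assignment as a tibble
#'
#' Membership of a cell in a unit is decided by cell-center containment; a
#' center exactly on a shared boundary belongs to the unit earliest in
#' `unit_id` sort order.
#'
#' @param unit_map An `rcmc_unit_map`.
#' @return A tibble with `cell_row`, `cell_col`, `unit_id` (NA outside all units).
#' @export
cell_assignment <- function(unit_map) {
  out <- cell_centers(unit_map$grid)[, c("cell_row", "cell_col")]
  idx <- as.vector(unit_map$assignment)
  out$unit_id <- unit_map$units$unit_id[idx]
  out
}

unit_cells <- function(unit_map, unit_idx) {
  which(as.vector(unit_map$assignment) == unit_idx)
}

#' Mean cell-center coordinates of each unit
#'
#' @param unit_map An `rcmc_unit_map`.
#' @return A two-column matrix (x, y), one row per unit in `unit_id` order.
#' @export
unit_centroids <- function(unit_map) {
  cc <- cell_centers(unit_map$grid)
  idx <- as.vector(unit_map$assignment)
  t(vapply(seq_len(nrow(unit_map$units)), function(i) {
    sel <- !is.na(idx) & idx == i
    c(mean(cc$x[sel]), mean(cc$y[sel]))
  }, numeric(2)))
}

#' Generate a synthetic partition of the grid extent into areal units
#'
#' Units are Voronoi cells of uniformly random seed points, clipped to the
#' grid extent: irregular but simple polygons resembling towns. Every grid
#' cell whose center lies in the extent is assigned to exactly one unit
#' (nearest seed; an exact tie goes to the unit earliest in `unit_id` sort
#' order).
#'
#' @param n_units Number of units (`>= 1`, at most the number of grid cells).
#' @param grid A [grid_geometry()].
#' @param seed Integer seed; identical seeds give bit-identical maps.
#' @return An `rcmc_unit_map` with a `units` tibble (`unit_id`, `polygon` as a
#'   list column of x/y matrices) and a cell-to-unit index matrix.
#' @examples
#' um <- make_geography(4, grid_geometry(20, 20), seed = 7)
#' table(cell_assignment(um)$unit_id)
#' @export
make_geography <- function(n_units, grid, seed = 1) {
  n_cells <- grid$n_rows * grid$n_cols
  if (n_units < 1) abort("`n_units` must be >= 1.")
  if (n_units > n_cells) {
    abort(sprintf("`n_units` (%d) exceeds the number of grid cells (%d).",
                  n_units, n_cells))
  }
  ext <- grid_extent(grid)
  set.seed(derive_seed(seed, 101))
  sx <- runif(n_units, ext["xmin"], ext["xmax"])
  sy <- runif(n_units, ext["ymin"], ext["ymax"])
  width <- max(2L, nchar(as.character(n_units)))
  ids <- sprintf(paste0("U%0", width, "d"), seq_len(n_units))

  cc <- cell_centers(grid)
  # nearest seed == containment in the Voronoi cell of that seed
  d2 <- outer(cc$x, sx, "-")^2 + outer(cc$y, sy, "-")^2
  assign_idx <- max.col(-d2, ties.method = "first") # ties -> lowest index = id order
  assignment <- matrix(as.integer(assign_idx), grid$n_rows, grid$n_cols)

  polys <- lapply(seq_len(n_units), function(i) {
    p <- voronoi_cell(i, sx, sy, ext)
    colnames(p) <- c("x", "y")
    p
  })
  units <- tibble(unit_id = ids, polygon = polys)
  new_unit_map(units, assignment, grid)
}

# ---- background rasters -----------------------------------------------------

#' Generate settlement-like background population rasters
#'
#' For each demographic stratum, distributes a total at-risk population over
#' the grid as integer per-cell counts by sampling individual locations from a
#' mixture of isotropic Gaussian blobs whose centers are uniform on the
#' extent. The result is spatially heterogeneous (clustered like settlements)
#' and sums exactly to the requested total.
#'
#' @param unit_map An `rcmc_unit_map` (supplies the shared grid).
#' @param strata Character vector of stratum labels (non-empty).
#' @param totals Named numeric vector: total population per stratum (`>= 0`).
#' @param n_blobs Number of settlement blobs per stratum (default 5); ignored
#'   when `blob_centers` is given.
#' @param blob_sd Gaussian blob standard deviation in map units (scalar, or a
#'   vector with one value per blob to mix compact villages with diffuse
#'   sprawl); default 8% of the shorter extent side.
#' @param blob_centers Optional two-column matrix of blob center coordinates,
#'   shared by all strata (e.g. [unit_centroids()] to center one settlement in
#'   each town); by default centers are uniform on the extent, independently
#'   per stratum.
#' @param seed Integer seed.
#' @return A named list of `rcmc_raster` objects, one per stratum.
#' @export
make_background <- function(unit_map, strata, totals, n_blobs = 5,
                            blob_sd = NULL, blob_centers = NULL, seed = 1) {
  if (length(strata) == 0) abort("`strata` must contain at least one stratum.")
  grid <- unit_map$grid
  ext <- grid_extent(grid)
  if (is.null(blob_sd)) {
    blob_sd <- 0.08 * min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
  }
  totals <- totals[strata]
  if (anyNA(totals) || any(totals < 0)) {
    abort("`totals` must provide a nonnegative total for every stratum.")
  }
  out <- vector("list", length(strata))
  names(out) <- strata
  for (s in seq_along(strata)) {
    set.seed(derive_seed(seed, 211, s))
    total <- as.integer(round(totals[s]))
    vals <- matrix(0, grid$n_rows, grid$n_cols)
    if (total > 0) {
      if (is.null(blob_centers)) {
        bx <- runif(n_blobs, ext["xmin"], ext["xmax"])
        by <- runif(n_blobs, ext["ymin"], ext["ymax"])
      } else {
        bx <- blob_centers[, 1]
        by <- blob_centers[, 2]
        n_blobs <- nrow(blob_centers)
      }
      sds <- rep_len(blob_sd, n_blobs)
      blob <- sample.int(n_blobs, total, replace = TRUE)
      eps <- grid$cell_size * 1e-6
      x <- pmin(pmax(rnorm(total, bx[blob], sds[blob]), ext["xmin"] + eps), ext["xmax"] - eps)
      y <- pmin(pmax(rnorm(total, by[blob], sds[blob]), ext["ymin"] + eps), ext["ymax"] - eps)
      cell <- xy_to_cell(grid, x, y)
      lin <- cell$cell_row + (cell$cell_col - 1L) * grid$n_rows
      counts <- tabulate(lin, nbins = grid$n_rows * grid$n_cols)
      vals <- matrix(as.double(counts), grid$n_rows, grid$n_cols)
    }
    out[[s]] <- rcmc_raster(vals, grid, label = strata[s])
  }
  out
}

# ---- aggregate counts -------------------------------------------------------

#' Specify a planted elevated-risk cluster
#'
#' Ground truth for recovery experiments: inside a disc the per-birth case
#' rate is multiplied by `risk_multiplier` (capped at probability 1).
#'
#' @param center_x,center_y Planar coordinates of the disc center.
#' @param radius Disc radius in map units (`> 0`).
#' @param risk_multiplier Rate multiplier inside the disc (`>= 1`).
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(center_x, center_y, radius, risk_multiplier) {
  if (radius <= 0) abort("`radius` must be > 0.")
  if (risk_multiplier < 1) abort("`risk_multiplier` must be >= 1.")
  structure(
    list(center_x = center_x, center_y = center_y,
         radius = radius, risk_multiplier = risk_multiplier),
    class = "cluster_spec"
  )
}

#' Draw aggregate cohort and case counts per unit and stratum
#'
#' Per unit x stratum the cohort count is binomial in the unit's summed
#' background weight with probability `births_per_capita`; the case count is
#' binomial in the cohort count at the stratum rate, inflated by the cluster
#' risk multiplier in proportion to the share of the unit's background inside
#' the cluster disc (the effective probability is capped at 1). The true
#' per-cell risk surface actually used is returned alongside for recovery
#' tests; it is never an input to estimation.
#'
#' @param unit_map An `rcmc_unit_map`.
#' @param backgrounds Named list of `rcmc_raster` (from [make_background()]).
#' @param stratum_rates Named numeric vector: per-stratum case probability.
#' @param births_per_capita Scalar or named per-stratum probability that a
#'   background individual contributes a cohort birth.
#' @param cluster Optional [cluster_spec()].
#' @param seed Integer seed.
#' @return A list with `aggregates` (tibble `unit_id`, `stratum`,
#'   `cohort_count`, `case_count`) and `risk` (named list of true per-cell
#'   risk `rcmc_raster`s).
#' @export
make_aggregates <- function(unit_map, backgrounds, stratum_rates,
                            births_per_capita = 0.05, cluster = NULL, seed = 1) {
  strata <- names(backgrounds)
  grid <- unit_map$grid
  rates <- stratum_rates[strata]
  if (anyNA(rates)) abort("`stratum_rates` must name every stratum in `backgrounds`.")
  bpc <- if (length(births_per_capita) == 1) {
    setNames(rep(births_per_capita, length(strata)), strata)
  } else births_per_capita[strata]

  cc <- cell_centers(grid)
  in_disc <- if (is.null(cluster)) rep(FALSE, nrow(cc)) else {
    (cc$x - cluster$center_x)^2 + (cc$y - cluster$center_y)^2 <= cluster$radius^2
  }
  mult <- if (is.null(cluster)) 1 else cluster$risk_multiplier

  rows <- list()
  risk <- list()
  set.seed(derive_seed(seed, 307))
  for (s in strata) {
    w <- as.vector(backgrounds[[s]]$values)
    risk_cells <- pmin(ifelse(in_disc, rates[s] * mult, rates[s]), 1)
    risk[[s]] <- rcmc_raster(matrix(risk_cells, grid$n_rows, grid$n_cols),
                             grid, label = paste0("risk_", s))
    for (i in seq_len(nrow(unit_map$units))) {
      cells <- unit_cells(unit_map, i)
      w_u <- w[cells]
      w_tot <- sum(w_u)
      cohort <- rbinom(1, size = as.integer(round(w_tot)), prob = bpc[s])
      share <- if (w_tot > 0) sum(w_u[in_disc[cells]]) / w_tot else 0
      p_case <- min(rates[s] * (1 + (mult - 1) * share), 1)
      cases <- rbinom(1, size = cohort, prob = p_case)
      rows[[length(rows) + 1L]] <- tibble(
        unit_id = unit_map$units$unit_id[i], stratum = s,
        cohort_count = as.integer(cohort), case_count = as.integer(cases)
      )
    }
  }
  agg <- bind_rows(rows) |> arrange(.data$unit_id, .data$stratum)
  list(aggregates = agg, risk = risk)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [make_geography()], [make_background()] and
#' [make_aggregates()] under one seed.
#'
#' @inheritParams make_geography
#' @inheritParams make_background
#' @inheritParams make_aggregates
#' @return A list: `unit_map`, `backgrounds`, `aggregates`, `risk`, `grid`.
#' @export
simulate_study <- function(n_units, grid, strata, totals, stratum_rates,
                           births_per_capita = 0.05, n_blobs = 5,
                           blob_sd = NULL, cluster = NULL, seed = 1) {
  um <- make_geography(n_units, grid, seed = seed)
  bg <- make_background(um, strata, totals, n_blobs = n_blobs,
                        blob_sd = blob_sd, seed = seed)
  ag <- make_aggregates(um, bg, stratum_rates,
                        births_per_capita = births_per_capita,
                        cluster = cluster, seed = seed)
  list(unit_map = um, backgrounds = bg, aggregates = ag$aggregates,
       risk = ag$risk, grid = grid)
}
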