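# Readers and writers. All formats are plain text: unit polygons as GeoJSON,
# rasters as ESRI ASCII grid (.asc; the header carries the grid geometry),
# count tables and birth points as CSV with JSON sidecars for run metadata.

# ---- GeoJSON unit maps ------------------------------------------------------

#' Write a unit map as GeoJSON
#'
#' One Polygon feature per unit with a `unit_id` property. Coordinates are in
#' the planar projected CRS of the analysis; a `crs` member marks them as
#' planar, and a non-standard `x_grid_geometry` member embeds the shared grid
#' so the file round-trips without a separate grid description.
#'
#' @param unit_map An `rcmc_unit_map`.
#' @param path Output file path.
#' @export
write_units <- function(unit_map, path) {
  features <- lapply(seq_len(nrow(unit_map$units)), function(i) {
    poly <- unit_map$units$polygon[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE]) # close the ring
    list(
      type = "Feature",
      properties = list(unit_id = unit_map$units$unit_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(k) {
          c(ring[k, 1], ring[k, 2])
        }))
      )
    )
  })
  g <- unit_map$grid
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = "urn:x-rcmc:planar")),
    x_grid_geometry = list(
      n_rows = g$n_rows, n_cols = g$n_cols, cell_size = g$cell_size,
      origin_x = g$origin_x, origin_y = g$origin_y
    ),
    features = features
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a unit map from GeoJSON
#'
#' Loads Polygon features with a `unit_id` property and recomputes the
#' cell-to-unit assignment by cell-center containment (first containing unit
#' in `unit_id` sort order wins on shared boundaries). Coordinates must be in
#' a projected planar CRS: files whose coordinates all fit in degree ranges
#' and carry no planar CRS marker are rejected with advice to reproject.
#'
#' @param path GeoJSON file path.
#' @param grid Optional [grid_geometry()]; defaults to the grid embedded by
#'   [write_units()].
#' @return An `rcmc_unit_map`.
#' @export
read_units <- function(path, grid = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(grid)) {
    gg <- obj$x_grid_geometry
    if (is.null(gg)) {
      abort("No `grid` supplied and the file embeds no grid geometry.")
    }
    grid <- grid_geometry(gg$n_rows, gg$n_cols, gg$cell_size,
                          gg$origin_x, gg$origin_y)
  }
  feats <- obj$features
  if (length(feats) == 0) abort("GeoJSON file contains no features.")
  ids <- vapply(feats, function(f) {
    id <- f$properties$unit_id
    if (is.null(id)) abort("A feature is missing the `unit_id` property.")
    as.character(id)
  }, character(1))
  polys <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      abort("Only Polygon geometries are supported.")
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    # drop the closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  crs_name <- tryCatch(obj$crs$properties$name, error = function(e) NULL)
  allx <- unlist(lapply(polys, function(p) p[, 1]))
  ally <- unlist(lapply(polys, function(p) p[, 2]))
  if (is.null(crs_name) && all(abs(allx) <= 180) && all(abs(ally) <= 90)) {
    abort(paste0(
      "Coordinates look geographic (degrees). The method requires a projected ",
      "planar CRS; reproject the units (and rasters) to a metric CRS first."
    ))
  }
  ord <- order(ids)
  ids <- ids[ord]
  polys <- polys[ord]
  if (anyDuplicated(ids)) abort("Duplicate unit_id values in GeoJSON.")

  cc <- cell_centers(grid)
  assign_idx <- rep(NA_integer_, nrow(cc))
  pts <- cbind(cc$x, cc$y)
  for (i in seq_along(polys)) {
    todo <- is.na(assign_idx)
    if (!any(todo)) break
    inside <- mgcv::in.out(polys[[i]], pts[todo, , drop = FALSE])
    assign_idx[which(todo)[inside]] <- i
  }
  units <- tibble(unit_id = ids, polygon = polys)
  new_unit_map(units, matrix(assign_idx, grid$n_rows, grid$n_cols), grid)
}

# ---- ASCII grid rasters -----------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#' `NA`/`NaN` cells are written as the nodata value.
#'
#' @param raster An `rcmc_raster`.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_raster <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[!is.finite(v)] <- nodata
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(v, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File path.
#' @param label Label for the resulting raster (default: file name stem).
#' @return An `rcmc_raster`; nodata cells become `NA`.
#' @export
read_raster <- function(path, label = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("Malformed ASCII grid header in '%s'.", path))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    abort(sprintf("ASCII grid '%s': expected %d values, found %d.",
                  path, hdr$nrows * hdr$ncols, length(vals)))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid <- grid_geometry(hdr$nrows, hdr$ncols, hdr$cellsize,
                        hdr$xllcorner, hdr$yllcorner)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  rcmc_raster(m, grid, label)
}

#' Read per-stratum background rasters
#'
#' All rasters must share one grid geometry; negative weights are an error;
#' nodata cells are treated as weight 0 (a message reports how many).
#'
#' @param paths Named character vector: stratum label -> ASCII grid path.
#' @return A list with `backgrounds` (named list of `rcmc_raster`) and `grid`.
#' @export
read_background <- function(paths) {
  if (length(paths) == 0 || is.null(names(paths))) {
    abort("`paths` must be a named vector: stratum -> raster path.")
  }
  out <- list()
  grid <- NULL
  for (s in names(paths)) {
    r <- read_raster(paths[[s]], label = s)
    if (is.null(grid)) {
      grid <- r$grid
    } else if (!grid_equal(r$grid, grid)) {
      abort(sprintf("Raster for stratum '%s' has a mismatched grid geometry.", s))
    }
    n_na <- sum(!is.finite(r$values))
    if (n_na > 0) {
      inform(sprintf("Stratum '%s': %d nodata cell(s) treated as weight 0.", s, n_na))
      r$values[!is.finite(r$values)] <- 0
    }
    if (any(r$values < 0)) {
      abort(sprintf("Raster for stratum '%s' contains negative weights.", s))
    }
    out[[s]] <- r
  }
  list(backgrounds = out, grid = grid)
}

# ---- aggregate tables and birth points --------------------------------------

#' Read an aggregate count table from CSV
#'
#' Expects the header `unit_id,stratum,cohort_count,case_count`. Validates
#' count invariants, duplicate (unit, stratum) pairs and — when a unit map is
#' supplied — that every unit exists.
#'
#' @param path CSV file path.
#' @param unit_map Optional `rcmc_unit_map` to validate unit ids against.
#' @return A tibble.
#' @export
read_aggregates <- function(path, unit_map = NULL) {
  agg <- readr::read_csv(path, col_types = readr::cols(
    unit_id = readr::col_character(), stratum = readr::col_character(),
    cohort_count = readr::col_integer(), case_count = readr::col_integer()
  ))
  if (!identical(names(agg), c("unit_id", "stratum", "cohort_count", "case_count"))) {
    abort("CSV must have header: unit_id,stratum,cohort_count,case_count")
  }
  check_aggregate_table(agg)
  if (!is.null(unit_map)) {
    bad <- !agg$unit_id %in% unit_map$units$unit_id
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("Row %d: unknown unit_id '%s'.", i, agg$unit_id[i]))
    }
  }
  agg
}

#' Write an aggregate count table to CSV
#'
#' @param agg Aggregate tibble.
#' @param path Output path.
#' @export
write_aggregates <- function(agg, path) {
  readr::write_csv(agg[, c("unit_id", "stratum", "cohort_count", "case_count")],
                   path)
  invisible(path)
}

#' Write one disaggregation realization to CSV with a metadata sidecar
#'
#' @param points Tibble from [disaggregate()].
#' @param path CSV output path; the sidecar is written at `<path>.meta.json`.
#' @export
write_birthpoints <- function(points, path) {
  readr::write_csv(
    points[, c("record_id", "unit_id", "stratum", "cell_row", "cell_col", "is_case")],
    path
  )
  g <- attr(points, "grid")
  meta <- list(
    iteration_index = attr(points, "iteration_index"),
    master_seed = attr(points, "master_seed"),
    grid = if (!is.null(g)) list(
      n_rows = g$n_rows, n_cols = g$n_cols, cell_size = g$cell_size,
      origin_x = g$origin_x, origin_y = g$origin_y
    )
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a disaggregation realization written by [write_birthpoints()]
#'
#' @param path CSV path (the `<path>.meta.json` sidecar is read if present).
#' @return A birth-point tibble with grid/seed attributes restored.
#' @export
read_birthpoints <- function(path) {
  pts <- readr::read_csv(path, col_types = readr::cols(
    record_id = readr::col_integer(), unit_id = readr::col_character(),
    stratum = readr::col_character(), cell_row = readr::col_integer(),
    cell_col = readr::col_integer(), is_case = readr::col_logical()
  ))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    attr(pts, "iteration_index") <- meta$iteration_index
    attr(pts, "master_seed") <- meta$master_seed
    if (!is.null(meta$grid)) {
      attr(pts, "grid") <- grid_geometry(
        meta$grid$n_rows, meta$grid$n_cols, meta$grid$cell_size,
        meta$grid$origin_x, meta$grid$origin_y
      )
    }
  }
  pts
}

#' Write a run manifest
#'
#' Records the configuration, seeds and package version of a pipeline run as
#' JSON text next to the output rasters.
#'
#' @param result An `rcmc_result`.
#' @param path Output path.
#' @export
write_manifest <- function(result, path) {
  meta <- c(result$config, list(
    thresholds = as.list(result$thresholds),
    rates = setNames(as.list(result$rates$rate), result$rates$stratum),
    package_version = as.character(utils::packageVersion("rcmcmap"))
  ))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
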