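# The RCMC core: every cohort member of every unit x stratum receives a
# random cell location, *restricted* to the cells of its source unit and
# *controlled* by the background raster (probability proportional to the cell
# weight); cases are then chosen within each unit x stratum by simple random
# sampling. Locations are cell centers: at 100 m cells, sub-cell placement
# would be spurious precision.

#' Place one unit-stratum's cohort births on the grid
#'
#' Draws `count` cell locations independently, with replacement across
#' births, from the multinomial over the unit's cells with probabilities
#' proportional to the background weights restricted to that unit. Multiple
#' births may share a cell (cells hold many at-risk individuals).
#'
#' Uses the current R random stream: seed control belongs to the caller
#' ([disaggregate()] derives one stream per iteration).
#'
#' @param unit_id Unit identifier present in `unit_map`.
#' @param count Number of births to place (`>= 0`).
#' @param background `rcmc_raster` of background weights for the stratum.
#' @param unit_map An `rcmc_unit_map`.
#' @param uniform_fallback If TRUE, a unit whose background is all zero gets a
#'   uniform distribution over its cells instead of an error. Off by default:
#'   a positive count over zero background signals an inconsistency between
#'   the count table and the background raster, and is surfaced, not hidden.
#' @return A tibble of `count` rows: `cell_row`, `cell_col`.
#' @export
assign_births <- function(unit_id, count, background, unit_map,
                          uniform_fallback = FALSE) {
  i <- match(unit_id, unit_map$units$unit_id)
  if (is.na(i)) abort(sprintf("Unknown unit_id '%s'.", unit_id))
  if (count < 0) abort("`count` must be >= 0.")
  cells <- unit_cells(unit_map, i)
  if (count == 0) {
    return(tibble(cell_row = integer(0), cell_col = integer(0)))
  }
  if (length(cells) == 0) {
    abort(sprintf("Unit '%s' contains no grid cells but has count %d.",
                  unit_id, count))
  }
  w <- as.vector(background$values)[cells]
  if (sum(w) <= 0) {
    if (!uniform_fallback) {
      abort(sprintf(
        "Unit '%s' has all-zero background weight but %d births to place; set `uniform_fallback = TRUE` to distribute uniformly.",
        unit_id, count
      ))
    }
    w <- rep(1, length(cells))
  }
  pick <- cells[sample.int(length(cells), count, replace = TRUE, prob = w)]
  n_rows <- unit_map$grid$n_rows
  tibble(
    cell_row = as.integer((pick - 1L) %% n_rows + 1L),
    cell_col = as.integer((pick - 1L) %/% n_rows + 1L)
  )
}

#' Flag cases among located births by simple random sampling
#'
#' Within one unit x stratum, a simple random sample without replacement of
#' size `case_count` from the located cohort births is flagged as the births
#' with defects. Uses the current R random stream.
#'
#' @param located Tibble of located births (any columns; rows are the cohort).
#' @param case_count Number of cases, `0 <= case_count <= nrow(located)`.
#' @return `located` with a logical `is_case` column added.
#' @export
select_cases <- function(located, case_count) {
  n <- nrow(located)
  if (case_count < 0 || case_count > n) {
    abort(sprintf("`case_count` (%d) must be between 0 and the cohort size (%d).",
                  case_count, n))
  }
  flags <- rep(FALSE, n)
  if (case_count > 0) flags[sample.int(n, case_count)] <- TRUE
  mutate(located, is_case = flags)
}

#' One restricted and controlled Monte Carlo disaggregation
#'
#' Runs [assign_births()] then [select_cases()] for every unit x stratum of
#' the aggregate table, producing one realization of approximated individual
#' birth locations. The iteration's random stream is derived deterministically
#' from `(master_seed, iteration_index)`, so iterations are reproducible and
#' mutually independent; re-running with the same pair is bit-identical.
#'
#' @param agg Aggregate tibble (`unit_id`, `stratum`, `cohort_count`,
#'   `case_count`).
#' @param backgrounds Named list of `rcmc_raster`, one per stratum.
#' @param unit_map An `rcmc_unit_map`.
#' @param iteration_index Index of this disaggregation iteration (`>= 1`).
#' @param master_seed Master seed of the run.
#' @param uniform_fallback Passed to [assign_births()].
#' @return A tibble (`record_id`, `unit_id`, `stratum`, `cell_row`,
#'   `cell_col`, `is_case`) with attributes `iteration_index`, `master_seed`
#'   and `grid`.
#' @export
disaggregate <- function(agg, backgrounds, unit_map, iteration_index = 1L,
                         master_seed = 1L, uniform_fallback = FALSE) {
  check_aggregate_table(agg)
  miss <- setdiff(unique(agg$stratum), names(backgrounds))
  if (length(miss)) {
    abort(paste0("No background raster for stratum: ", paste(miss, collapse = ", ")))
  }
  miss_u <- setdiff(unique(agg$unit_id), unit_map$units$unit_id)
  if (length(miss_u)) {
    abort(paste0("Aggregate table references unknown unit(s): ",
                 paste(miss_u, collapse = ", ")))
  }
  agg <- arrange(agg, .data$unit_id, .data$stratum)
  set.seed(derive_seed(master_seed, iteration_index))
  parts <- vector("list", nrow(agg))
  for (r in seq_len(nrow(agg))) {
    loc <- assign_births(agg$unit_id[r], agg$cohort_count[r],
                         backgrounds[[agg$stratum[r]]], unit_map,
                         uniform_fallback = uniform_fallback)
    loc <- select_cases(loc, agg$case_count[r])
    if (nrow(loc)) {
      loc$unit_id <- agg$unit_id[r]
      loc$stratum <- agg$stratum[r]
      parts[[r]] <- loc
    }
  }
  out <- bind_rows(parts)
  if (nrow(out) == 0) {
    out <- tibble(cell_row = integer(0), cell_col = integer(0),
                  is_case = logical(0), unit_id = character(0),
                  stratum = character(0))
  }
  out <- out |>
    mutate(record_id = row_number()) |>
    select("record_id", "unit_id", "stratum", "cell_row", "cell_col", "is_case")
  attr(out, "iteration_index") <- as.integer(iteration_index)
  attr(out, "master_seed") <- as.integer(master_seed)
  attr(out, "grid") <- unit_map$grid
  out
}
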