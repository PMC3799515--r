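#' Stratum case rates from an aggregate count table
#'
#' Sums cohort and case counts over units within each stratum and forms the
#' stratum rate (total cases / total cohort), kept at full precision. These
#' statewide rates drive both the kernel enclosure thresholds and the
#' indirect standardization of the combined intensity surface.
#'
#' @param agg Aggregate tibble with columns `unit_id`, `stratum`,
#'   `cohort_count`, `case_count`.
#' @return A tibble with one row per stratum: `stratum`, `case_total`,
#'   `cohort_total`, `rate`.
#' @examples
#' agg <- tibble::tibble(
#'   unit_id = "U1", stratum = c("15-39", "40-49"),
#'   cohort_count = c(91906L, 2840L), case_count = c(1337L, 55L)
#' )
#' compute_stratum_rates(agg)
#' @export
compute_stratum_rates <- function(agg) {
  check_aggregate_table(agg)
  out <- agg |>
    group_by(.data$stratum) |>
    summarise(
      case_total = sum(.data$case_count),
      cohort_total = sum(.data$cohort_count),
      .groups = "drop"
    ) |>
    mutate(rate = .data$case_total / .data$cohort_total) |>
    arrange(.data$stratum)
  bad <- out$stratum[out$cohort_total == 0]
  if (length(bad)) {
    abort(sprintf("Stratum '%s' has zero total cohort; its rate is undefined.",
                  bad[1]))
  }
  out
}

#' Display stratum rates rounded to four decimals
#'
#' Rates are carried at full precision internally; this helper formats them
#' the way registry tables print them.
#'
#' @param rates Output of [compute_stratum_rates()].
#' @return The input with an added character column `rate_display`.
#' @export
rate_display <- function(rates) {
  mutate(rates, rate_display = sprintf("%.4f", .data$rate))
}

#' Kernel enclosure threshold from a stratum rate
#'
#' The case-side adaptive kernel around each case grows until it encloses the
#' amount of background cohort that supports one expected case: the rounded
#' reciprocal of the stratum rate (round half up, so a rate of 0.0145 gives a
#' threshold of 69 births).
#'
#' @param rate Stratum case rate in (0, 1].
#' @return Integer number of cohort births to enclose.
#' @examples
#' kernel_threshold(0.0145) # 69
#' @export
kernel_threshold <- function(rate) {
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0 || rate > 1) {
    abort("`rate` must be a single value in (0, 1].")
  }
  as.integer(floor(1 / rate + 0.5))
}

check_aggregate_table <- function(agg) {
  need <- c("unit_id", "stratum", "cohort_count", "case_count")
  miss <- setdiff(need, names(agg))
  if (length(miss)) {
    abort(paste0("Aggregate table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(agg$case_count > agg$cohort_count)) {
    i <- which(agg$case_count > agg$cohort_count)[1]
    abort(sprintf("Row %d (%s, %s): case_count exceeds cohort_count.",
                  i, agg$unit_id[i], agg$stratum[i]))
  }
  if (any(agg$cohort_count < 0) || any(agg$case_count < 0)) {
    abort("Counts must be nonnegative.")
  }
  dup <- duplicated(agg[, c("unit_id", "stratum")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("Duplicate (unit_id, stratum) pair at row %d: (%s, %s).",
                  i, agg$unit_id[i], agg$stratum[i]))
  }
  invisible(agg)
}
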