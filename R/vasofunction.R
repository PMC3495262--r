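## Reduction of isolated-arteriole diameter measurements to basal tone and
## percent-of-maximal-dilation dose-response curves.

#' Basal tone
#'
#' Resting constriction of a pressurized arteriole, expressed as the
#' resting diameter as a percentage of the maximal (sodium nitroprusside)
#' diameter: 100 * resting / max.
#'
#' @param resting_d resting diameter (um), 0 < resting <= max.
#' @param max_d maximal diameter (um).
#' @return percent of maximal diameter in (0, 100].
#' @export
basal_tone <- function(resting_d, max_d) {
  if (any(resting_d <= 0) || any(resting_d > max_d))
    stop("contract violation: need 0 < resting_d <= max_d")
  100 * resting_d / max_d
}

#' Percent of maximal dilation
#'
#' Diameter change normalized to the sodium-nitroprusside dilation:
#' 100 * (d - d_baseline) / (d_max - d_baseline), where the baseline is
#' the pre-agonist resting (toned) diameter.
#'
#' @param d measured diameter (um).
#' @param d_baseline resting diameter (um).
#' @param d_max maximal diameter (um), > d_baseline.
#' @return percent of maximal dilation (0 at baseline, 100 at maximum).
#' @export
percent_max_dilation <- function(d, d_baseline, d_max) {
  if (any(d_max <= d_baseline))
    stop("contract violation: d_max must exceed d_baseline")
  100 * (d - d_baseline) / (d_max - d_baseline)
}

#' Summarize dose-response records by group
#'
#' Computes each vessel's basal tone and per-dose percent of maximal
#' dilation, then per-group (condition x treatment) means and standard
#' errors at every dose, plus a basal-tone summary.  Basal tone is averaged
#' per vessel (mean of per-vessel ratios).  All vessels must share one dose
#' grid.  The SEM of a single-vessel group is reported as 0 and flagged.
#'
#' @param records list of `dose_response_record` (see
#'   [make_dose_response()]).
#' @return object of class `curve_summary`: list with `curves` (tibble:
#'   condition, treatment, dose_log10_M, mean_pct, sem_pct, n),
#'   `basal_tone` (tibble: condition, treatment, mean_pct, sem_pct, n,
#'   single_vessel flag) and `per_vessel` (tibble of per-vessel tones).
#' @export
summarize_curves <- function(records) {
  stopifnot(length(records) >= 1L)
  grids <- lapply(records, function(r) r$doses_log10_M)
  if (!all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1))))
    stop("grid error: mismatched dose grids across vessels")
  per_vessel <- dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(
      vessel_id = r$vessel_id, condition = r$condition,
      treatment = r$treatment,
      basal_tone_pct = basal_tone(r$resting_diameter_um, r$max_diameter_um))
  }))
  long <- dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(
      vessel_id = r$vessel_id, condition = r$condition,
      treatment = r$treatment, dose_log10_M = r$doses_log10_M,
      pct = percent_max_dilation(r$diameters_um, r$resting_diameter_um,
                                 r$max_diameter_um))
  }))
  curves <- long |>
    dplyr::group_by(.data$condition, .data$treatment, .data$dose_log10_M) |>
    dplyr::summarise(mean_pct = mean(.data$pct), sem_pct = sem(.data$pct),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$condition, .data$treatment, .data$dose_log10_M)
  tone <- per_vessel |>
    dplyr::group_by(.data$condition, .data$treatment) |>
    dplyr::summarise(mean_pct = mean(.data$basal_tone_pct),
                     sem_pct = sem(.data$basal_tone_pct),
                     n = dplyr::n(),
                     single_vessel = dplyr::n() == 1L, .groups = "drop")
  structure(list(curves = curves, basal_tone = tone,
                 per_vessel = per_vessel),
            class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat("<curve_summary>\n")
  print(x$basal_tone)
  cat("curves across", length(unique(x$curves$dose_log10_M)), "doses\n")
  invisible(x)
}
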