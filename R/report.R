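## Cohort-level report assembly: joins the per-animal measurement tables
## and produces per-group summary blocks with star annotations.

#' Assemble a cohort report
#'
#' Joins geometry, stain-fraction and nuclei tables on the
#' (condition, week, animal) key into one long-format table, and computes
#' per-group summary blocks (mean, SEM, n per measure) with significance
#' stars for the condition contrast within each week (Welch t-tests,
#' Bonferroni-adjusted over the family of contrasts per measure).  Empty
#' input tables are skipped and flagged.  Output ordering is deterministic
#' and independent of input row order; a designated group can be dropped
#' (mirroring the exclusion of sham controls from reporting).
#'
#' @param geometry_tbl,fraction_tbl,nuclei_tbl data frames keyed by
#'   condition, week, animal, with measure columns; any may be `NULL` or
#'   empty (flagged).
#' @param curve_summary optional `curve_summary` (see
#'   [summarize_curves()]) attached verbatim.
#' @param drop_condition optional condition label excluded from the report.
#' @return object of class `cohort_report`: list with `long` (condition,
#'   week, animal, measure, value), `summary` (per measure x group: mean,
#'   sem, n), `contrasts` (per measure x week condition contrasts with
#'   adjusted p and stars), `curves`, `flags`.
#' @export
build_report <- function(geometry_tbl = NULL, fraction_tbl = NULL,
                         nuclei_tbl = NULL, curve_summary = NULL,
                         drop_condition = NULL) {
  key <- c("condition", "week", "animal")
  flags <- character(0)
  pivot <- function(tbl, label) {
    if (is.null(tbl) || nrow(as.data.frame(tbl)) == 0L) {
      flags <<- c(flags, paste0("missing ", label, " table"))
      return(NULL)
    }
    tbl <- tibble::as_tibble(tbl)
    if (!all(key %in% names(tbl)))
      stop("join error: ", label, " table lacks the (condition, week, ",
           "animal) key")
    measure_cols <- setdiff(names(tbl),
                            c(key, "seed",
                              grep("_true_", names(tbl), value = TRUE)))
    measure_cols <- measure_cols[vapply(tbl[measure_cols], is.numeric,
                                        logical(1))]
    tidyr::pivot_longer(tbl[c(key, measure_cols)],
                        dplyr::all_of(measure_cols),
                        names_to = "measure", values_to = "value")
  }
  long <- dplyr::bind_rows(
    pivot(geometry_tbl, "geometry"),
    pivot(fraction_tbl, "stain fraction"),
    pivot(nuclei_tbl, "nuclei")
  )
  if (is.null(long) || nrow(long) == 0L)
    stop("join error: no non-empty input tables")
  if (!is.null(drop_condition)) {
    long <- dplyr::filter(long, .data$condition != drop_condition)
    flags <- c(flags, paste0("dropped condition ", drop_condition))
  }
  long <- dplyr::distinct(long) |>
    dplyr::arrange(.data$measure, .data$condition, .data$week, .data$animal)

  summary_tbl <- long |>
    dplyr::group_by(.data$measure, .data$condition, .data$week) |>
    dplyr::summarise(mean = mean(.data$value), sem = sem(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$measure, .data$condition, .data$week)

  contrasts <- long |>
    dplyr::group_by(.data$measure, .data$week) |>
    dplyr::group_modify(function(d, g) {
      conds <- sort(unique(d$condition))
      if (length(conds) != 2L) return(tibble::tibble())
      y1 <- d$value[d$condition == conds[1]]
      y2 <- d$value[d$condition == conds[2]]
      if (length(y1) < 2L || length(y2) < 2L || (sd(y1) == 0 && sd(y2) == 0))
        return(tibble::tibble())
      tibble::tibble(group1 = conds[1], group2 = conds[2],
                     p_raw = stats::t.test(y1, y2)$p.value)
    }) |>
    dplyr::ungroup()
  if (nrow(contrasts)) {
    contrasts <- contrasts |>
      dplyr::group_by(.data$measure) |>
      dplyr::mutate(p_adjusted = bonferroni_adjust(.data$p_raw,
                                                   dplyr::n())) |>
      dplyr::ungroup() |>
      dplyr::mutate(stars = star_code(.data$p_adjusted)) |>
      dplyr::arrange(.data$measure, .data$week)
  }
  structure(list(long = long, summary = summary_tbl,
                 contrasts = contrasts, curves = curve_summary,
                 flags = flags),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", length(unique(x$long$measure)), " measures, ",
      nrow(x$long), " values", "\n", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = "; "),
                           "\n", sep = "")
  invisible(x)
}
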