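## Synthetic arteriole dose-response generator.
##
## Ground truth follows a four-parameter logistic in log10 molar dose:
##   d(x) = resting + (max - resting) / (1 + 10^(hill * (ec50 - x)))
## so the dilation is 0 at baseline, 50% of maximal at the EC50 and
## saturates at the sodium-nitroprusside maximum.  The logistic is a
## generator-side construct only; the analysis side never fits it.

#' Default adenosine dose grid (log10 molar)
#'
#' Eleven half-decade steps spanning 0.1 nmol/l to 10 umol/l.
#' @return numeric vector of log10 molar concentrations.
#' @export
adenosine_doses <- function() seq(-10, -5, by = 0.5)

#' Simulate isolated-arteriole dose-response records
#'
#' Generates per-vessel diameter series under a sigmoidal dilation model:
#' diameters rise from the resting (toned) diameter toward the maximal
#' diameter with increasing adenosine dose; the sodium-nitroprusside (SNP)
#' diameter is the maximal diameter plus measurement noise.
#'
#' @param n_vessels number of vessels (one per animal).
#' @param resting_d,max_d resting and maximal diameter in um
#'   (0 < resting < max).
#' @param ec50_log10 log10 molar dose of half-maximal dilation.
#' @param hill_slope Hill slope of the logistic (> 0).
#' @param noise_sd SD of additive diameter noise in um.
#' @param seed RNG seed.
#' @param doses dose grid in log10 molar, strictly increasing.
#' @param condition,treatment group labels attached to every record
#'   (condition NT/HT; treatment none or l-NAME).
#' @param efficacy top plateau of the dilation as a fraction of the full
#'   resting-to-max span (1 = dilates fully; < 1 models attenuated,
#'   e.g. NOS-inhibited, responses).
#' @return a list of `dose_response_record` objects; see
#'   [dose_response_table()] for the tidy long form.
#' @export
make_dose_response <- function(n_vessels, resting_d, max_d,
                               ec50_log10 = -7.5, hill_slope = 1,
                               noise_sd = 0, seed = 1L,
                               doses = adenosine_doses(),
                               condition = "NT", treatment = "none",
                               efficacy = 1) {
  if (!(resting_d > 0 && resting_d < max_d))
    stop("contract violation: need 0 < resting_d < max_d")
  stopifnot(all(diff(doses) > 0), n_vessels >= 1, efficacy >= 0,
            efficacy <= 1, hill_slope > 0)
  withr::with_seed(seed, {
    lapply(seq_len(n_vessels), function(v) {
      span <- (max_d - resting_d) * efficacy
      frac <- 1 / (1 + 10^(hill_slope * (ec50_log10 - doses)))
      d <- resting_d + span * frac + stats::rnorm(length(doses), 0, noise_sd)
      rec <- list(
        vessel_id = sprintf("%s_%s_v%02d", condition, treatment, v),
        condition = condition,
        treatment = treatment,
        resting_diameter_um = resting_d + stats::rnorm(1, 0, noise_sd),
        max_diameter_um = max_d + stats::rnorm(1, 0, noise_sd),
        doses_log10_M = doses,
        diameters_um = d
      )
      if (noise_sd == 0) {           # keep the noiseless contract exact
        rec$resting_diameter_um <- resting_d
        rec$max_diameter_um <- max_d
      }
      structure(rec, class = "dose_response_record")
    })
  })
}

#' Tidy long table of dose-response records
#'
#' One row per measurement with `row_type` in resting/dose/snp, mirroring
#' the tabular interchange format for myography data.
#'
#' @param records list of `dose_response_record`.
#' @return a tibble with columns vessel_id, condition, treatment,
#'   dose_log10_M (NA for resting/snp rows), diameter_um, row_type.
#' @export
dose_response_table <- function(records) {
  dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(
      vessel_id = r$vessel_id,
      condition = r$condition,
      treatment = r$treatment,
      dose_log10_M = c(NA_real_, r$doses_log10_M, NA_real_),
      diameter_um = c(r$resting_diameter_um, r$diameters_um,
                      r$max_diameter_um),
      row_type = c("resting", rep("dose", length(r$doses_log10_M)), "snp")
    )
  }))
}
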