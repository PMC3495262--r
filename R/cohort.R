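## Study-design and cohort simulation: reproducible sets of phantoms keyed
## by (condition, week, animal), with deterministic per-animal seeds derived
## from one master seed and lognormal between-animal thickness variability.

#' Define a simulated study design
#'
#' A design holds the group table (condition x week with per-group animal
#' counts), one [phantom_spec()] preset per group, a master seed and the
#' between-animal biological variability of layer thicknesses.
#'
#' @param groups data frame with columns `condition` (e.g. NT/HT), `week`
#'   and `n_animals` (>= 1); group keys must be unique.
#' @param presets named list of [phantom_spec()]s keyed
#'   `"<condition>_<week>"`, one per group row.
#' @param master_seed integer master seed; per-phantom seeds are derived
#'   deterministically from it and are pairwise distinct.
#' @param thickness_cv lognormal coefficient of variation applied
#'   independently to each animal's layer thicknesses (default 0.05,
#'   a realistic between-animal spread for a controlled cohort).
#' @return object of class `study_design`.
#' @export
study_design <- function(groups, presets, master_seed = 1L,
                         thickness_cv = 0.05) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("condition", "week", "n_animals") %in% names(groups)),
            all(groups$n_animals >= 1))
  key <- paste(groups$condition, groups$week, sep = "_")
  if (anyDuplicated(key))
    stop("design error: duplicate (condition, week) group keys")
  missing <- setdiff(key, names(presets))
  if (length(missing))
    stop("design error: no preset for group(s) ",
         paste(missing, collapse = ", "))
  stopifnot(all(vapply(presets, inherits, logical(1), "phantom_spec")),
            thickness_cv >= 0)
  structure(list(groups = groups, presets = presets,
                 master_seed = as.integer(master_seed),
                 thickness_cv = as.numeric(thickness_cv)),
            class = "study_design")
}

## deterministic, distinct, 32-bit-safe per-animal seed
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Simulate a cohort of artery phantoms
#'
#' Expands a [study_design()] into one phantom per animal.  Each animal's
#' layer thicknesses are the group preset times independent lognormal
#' factors with CV `thickness_cv` (unit mean), and each animal gets a
#' distinct seed derived from the master seed, so the whole cohort is
#' reproducible bit-for-bit.
#'
#' @param design a [study_design()].
#' @param render if `TRUE`, rasterize every phantom
#'   (see [make_artery_phantom()]); if `FALSE`, return only the tabular
#'   ground truth (true per-animal thicknesses and presets) — the
#'   generator's statistical model without pixels, suitable for
#'   simulation studies at scale.
#' @return a list with `cohort` (tibble keyed condition/week/animal, with
#'   seeds and true layer thicknesses) and, when `render = TRUE`,
#'   `phantoms` — a named list of [make_artery_phantom()] outputs keyed
#'   `"<condition>_<week>_<animal>"`.
#' @export
make_cohort <- function(design, render = TRUE) {
  stopifnot(inherits(design, "study_design"))
  g <- design$groups
  cv <- design$thickness_cv
  rows <- list(); phantoms <- list()
  idx <- 0L
  for (i in seq_len(nrow(g))) {
    key <- paste(g$condition[i], g$week[i], sep = "_")
    preset <- design$presets[[key]]
    for (a in seq_len(g$n_animals[i])) {
      idx <- idx + 1L
      seed_a <- derive_seed(design$master_seed, idx)
      t_true <- withr::with_seed(seed_a, {
        if (cv > 0)
          preset$layer_thicknesses_um *
            exp(stats::rnorm(3, -cv^2 / 2, cv))
        else preset$layer_thicknesses_um
      })
      spec_a <- preset
      spec_a$layer_thicknesses_um <- t_true
      spec_a$seed <- seed_a
      akey <- sprintf("%s_a%02d", key, a)
      rows[[akey]] <- tibble::tibble(
        condition = g$condition[i], week = g$week[i], animal = a,
        seed = seed_a,
        intima_true_um = t_true[["intima"]],
        media_true_um = t_true[["media"]],
        adventitia_true_um = t_true[["adventitia"]],
        wall_true_um = sum(t_true),
        inner_radius_true_um = preset$inner_radius_um
      )
      if (render) phantoms[[akey]] <- make_artery_phantom(spec_a)
    }
  }
  cohort <- dplyr::bind_rows(rows)
  if (render) list(cohort = cohort, phantoms = phantoms)
  else list(cohort = cohort)
}
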