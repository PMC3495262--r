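## End-to-end measurement pipeline over rendered phantoms: lumen detection,
## perivascular cropping, layer masks (annotation hand-off), geometry,
## stain fractions and nuclei statistics, per image set.

#' Measure one phantom through the full pipeline
#'
#' Runs the analysis chain exactly as it would run on real images: the
#' lumen is detected by seeded flood fill on the VVG channel (lumen filled
#' black), perivascular content is cropped with the adventitial contour
#' (taken from the annotation hand-off — here the phantom's outer
#' boundary), layer masks are assembled from the media/adventitia
#' annotations, and geometry, stain fractions and nuclei statistics are
#' computed from the resulting masks.  Ground truth is never consulted for
#' any intensity decision; annotations stand in for the manual cropping
#' steps.
#'
#' @param phantom output of [make_artery_phantom()].
#' @param control optional matched [make_negative_control()] image set;
#'   when present, fluorescence thresholds are calibrated against it,
#'   otherwise a fixed mid-range threshold of 110 is used.
#' @param lumen_tolerance flood-fill tolerance (default 10).
#' @return one-row tibble of measured quantities (geometry in um, stain
#'   fractions, nuclei count/density).
#' @export
measure_phantom <- function(phantom, control = NULL, lumen_tolerance = 10) {
  img <- phantom$images
  scale <- img$pixel_scale_um_per_px
  vvg <- img$channels$vvg
  seed_pt <- round(colMeans(mask_coords(phantom$masks$lumen)))
  lum <- detect_lumen(vvg, seed_pt, tolerance = lumen_tolerance)
  contour <- outer_contour(phantom$masks)      # annotation hand-off
  crop <- crop_perivascular(vvg, contour, lum$mask)
  masks <- assemble_layer_masks(crop$wall, lum$mask,
                                phantom$masks$media & crop$wall,
                                phantom$masks$adventitia & crop$wall)
  geom <- ring_geometry(masks, scale)
  layers <- layer_ring_thicknesses(masks, scale)

  frac <- function(ch, st) {
    thr <- if (!is.null(control)) {
      calibrate_threshold(img$channels[[ch]][masks$wall],
                          control$channels[[ch]][masks$wall],
                          batch_key = img$batch_key)$threshold
    } else 110
    area_fraction(img$channels[[ch]], masks$wall, thr, stain = st)$fraction
  }
  elast <- elastin_fraction_vvg(vvg, masks$wall)$fraction
  cents <- detect_nuclei(img$channels$dapi)
  dens <- cell_density(nrow(cents), sum(masks$wall) * scale^2)

  tibble::tibble(
    inner_radius_um = geom$inner_radius_um,
    outer_radius_um = geom$outer_radius_um,
    wall_thickness_um = geom$mean_thickness_ring_um,
    intima_um = layers[["intima"]],
    media_um = layers[["media"]],
    adventitia_um = layers[["adventitia"]],
    hydraulic_diameter_um = geom$hydraulic_diameter_um,
    sma_fraction = frac("sma", "sma"),
    cd34_fraction = frac("cd34", "cd34"),
    mac387_fraction = frac("mac387", "mac387"),
    elastin_fraction = elast,
    nuclei_count = nrow(cents),
    nuclei_density_per_um2 = dens
  )
}

#' Measure every phantom of a rendered cohort
#'
#' Applies [measure_phantom()] to each animal of a [make_cohort()] result
#' and binds the measurements to the cohort key table.
#'
#' @param cohort_result output of `make_cohort(design, render = TRUE)`.
#' @return tibble: cohort keys joined with per-animal measurements.
#' @export
measure_cohort <- function(cohort_result) {
  stopifnot(!is.null(cohort_result$phantoms))
  meas <- dplyr::bind_rows(lapply(cohort_result$phantoms, measure_phantom))
  dplyr::bind_cols(cohort_result$cohort, meas)
}
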