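#' Phantom specification for a synthetic artery cross-section
#'
#' A `phantom_spec` fixes every parameter of one synthetic artery phantom:
#' wall architecture class, lumen size, per-layer thicknesses, the number of
#' elastic lamellae, constituent area fractions of the wall, nuclei density,
#' pixel scale, channel noise, lumen eccentricity and the RNG seed.  The
#' generator is fully deterministic given the spec.
#'
#' @param artery_class one of `"elastic_many_lamellae"`,
#'   `"muscular_two_lamellae"`, `"muscular_one_lamella"` — the three wall
#'   architectures of a large elastic artery, a coronary-type muscular artery
#'   with two elastic lamellae, and a cerebral-type muscular artery with a
#'   single lamella.
#' @param inner_radius_um lumen equivalent radius in micrometres (> 0).
#' @param layer_thicknesses_um numeric length 3: intima, media, adventitia
#'   thickness in micrometres, all > 0.
#' @param n_lamellae number of elastic lamellae rendered as thin
#'   high-elastin rings across the media (>= 1).
#' @param constituent_fractions named numeric with entries `elastin`, `sma`,
#'   `collagen`, `cd34`, `mac387`, each in \[0, 1\]: target area fraction of
#'   the wall painted positive in the corresponding channel.
#' @param nuclei_density_cells_per_um2 nuclei per square micrometre of wall
#'   (> 0).
#' @param pixel_scale_um_per_px micrometres per pixel (> 0).
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise, in 8-bit intensity units.
#' @param eccentricity lumen eccentricity >= 0; 0 gives a perfect circle,
#'   larger values stretch the lumen into an area-preserving ellipse with
#'   semi-axes `r(1+e)` and `r/(1+e)`.
#' @param seed integer RNG seed.
#'
#' @return an object of class `phantom_spec`.
#' @seealso [phantom_preset()] for paper-motivated per-class presets,
#'   [make_artery_phantom()] for rendering.
#' @export
phantom_spec <- function(artery_class = c("elastic_many_lamellae",
                                          "muscular_two_lamellae",
                                          "muscular_one_lamella"),
                         inner_radius_um,
                         layer_thicknesses_um,
                         n_lamellae = NULL,
                         constituent_fractions = c(elastin = 0.1, sma = 0.3,
                                                   collagen = 0.2, cd34 = 0.02,
                                                   mac387 = 0.01),
                         nuclei_density_cells_per_um2 = 0.004,
                         pixel_scale_um_per_px = 1,
                         noise_sd = 10,
                         eccentricity = 0,
                         seed = 1L) {
  artery_class <- match.arg(artery_class)
  if (is.null(n_lamellae)) {
    n_lamellae <- switch(artery_class,
                         elastic_many_lamellae = 8L,
                         muscular_two_lamellae = 2L,
                         muscular_one_lamella  = 1L)
  }
  stopifnot(
    "inner radius must be positive" = inner_radius_um > 0,
    "exactly three layer thicknesses required" =
      length(layer_thicknesses_um) == 3L,
    "all layer thicknesses must be positive" = all(layer_thicknesses_um > 0),
    "n_lamellae must be >= 1" = n_lamellae >= 1,
    "pixel scale must be positive" = pixel_scale_um_per_px > 0,
    "noise_sd must be >= 0" = noise_sd >= 0,
    "eccentricity must be >= 0" = eccentricity >= 0,
    "nuclei density must be positive" = nuclei_density_cells_per_um2 > 0
  )
  needed <- c("elastin", "sma", "collagen", "cd34", "mac387")
  if (!all(needed %in% names(constituent_fractions)))
    stop("constituent_fractions must name: ",
         paste(needed, collapse = ", "))
  fr <- constituent_fractions[needed]
  if (any(fr < 0 | fr > 1))
    stop("each constituent fraction must lie in [0, 1]")
  structure(list(
    artery_class = artery_class,
    inner_radius_um = as.numeric(inner_radius_um),
    layer_thicknesses_um = setNames(as.numeric(layer_thicknesses_um),
                                    c("intima", "media", "adventitia")),
    n_lamellae = as.integer(n_lamellae),
    constituent_fractions = fr,
    nuclei_density_cells_per_um2 = as.numeric(nuclei_density_cells_per_um2),
    pixel_scale_um_per_px = as.numeric(pixel_scale_um_per_px),
    noise_sd = as.numeric(noise_sd),
    eccentricity = as.numeric(eccentricity),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Per-class phantom presets
#'
#' Ready-made [phantom_spec()]s for the three wall architectures, with
#' constituent fractions and nuclei densities set to the normotensive
#' baseline values reported for the proximal descending aorta (elastic,
#' many-lamellae), the left anterior descending coronary artery (muscular,
#' two lamellae) and the middle cerebral artery (muscular, one lamella):
#' elastin/SMA/collagen percentages 47.9/25.8/12.8, 8.0/29.2/49.0 and
#' 2.8/31.8/30.6, and nuclei densities 0.000127, 0.00378 and 0.005497
#' cells/um^2 respectively.  Geometries are scaled-down but keep realistic
#' layer proportions.
#'
#' @param artery_class the wall architecture class.
#' @param seed RNG seed passed through to the spec.
#' @param ... overrides forwarded to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(artery_class = c("elastic_many_lamellae",
                                            "muscular_two_lamellae",
                                            "muscular_one_lamella"),
                           seed = 1L, ...) {
  artery_class <- match.arg(artery_class)
  base <- switch(artery_class,
    elastic_many_lamellae = list(
      inner_radius_um = 150,
      layer_thicknesses_um = c(10, 60, 30),
      constituent_fractions = c(elastin = 0.479, sma = 0.258,
                                collagen = 0.128, cd34 = 0.02, mac387 = 0.01),
      nuclei_density_cells_per_um2 = 0.000127),
    muscular_two_lamellae = list(
      inner_radius_um = 60,
      layer_thicknesses_um = c(5, 30, 15),
      constituent_fractions = c(elastin = 0.080, sma = 0.292,
                                collagen = 0.490, cd34 = 0.02, mac387 = 0.01),
      nuclei_density_cells_per_um2 = 0.00378),
    muscular_one_lamella = list(
      inner_radius_um = 40,
      layer_thicknesses_um = c(4, 20, 10),
      constituent_fractions = c(elastin = 0.028, sma = 0.318,
                                collagen = 0.306, cd34 = 0.02, mac387 = 0.01),
      nuclei_density_cells_per_um2 = 0.005497))
  args <- utils::modifyList(c(list(artery_class = artery_class, seed = seed),
                              base),
                            list(...))
  do.call(phantom_spec, args)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$artery_class, "\n",
      "  inner radius: ", x$inner_radius_um, " um; layers (i/m/a): ",
      paste(x$layer_thicknesses_um, collapse = "/"), " um\n",
      "  lamellae: ", x$n_lamellae,
      "; eccentricity: ", x$eccentricity,
      "; scale: ", x$pixel_scale_um_per_px, " um/px; seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}
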