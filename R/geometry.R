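## Radii and wall/layer thicknesses by the two routes used for whole rings
## (equivalent radii from areas) and transmural strips (column-mean
## thickness), with circumference- and hydraulic-diameter-based radii
## reported alongside for sensitivity checks.

#' Equivalent radius of a circle with the given area
#'
#' r = sqrt(area / pi).
#' @param area area (any squared length unit); must be >= 0.
#' @return radius in the matching length unit.
#' @export
equivalent_radius_from_area <- function(area) {
  if (any(area < 0)) stop("contract violation: negative area")
  sqrt(area / pi)
}

#' Radius of a circle with the given circumference
#'
#' r = perimeter / (2 pi).
#' @param perimeter perimeter (length); >= 0.
#' @return radius.
#' @export
radius_from_perimeter <- function(perimeter) {
  if (any(perimeter < 0)) stop("contract violation: negative perimeter")
  perimeter / (2 * pi)
}

#' Hydraulic diameter
#'
#' D_h = 4 area / perimeter; equals the geometric diameter for a circle
#' and the side length for a square.
#' @param area cross-sectional area.
#' @param perimeter wetted perimeter (> 0).
#' @return hydraulic diameter.
#' @export
hydraulic_diameter <- function(area, perimeter) {
  if (any(perimeter <= 0))
    stop("contract violation: perimeter must be positive")
  4 * area / perimeter
}

#' Whole-ring geometry summary from lumen and wall masks
#'
#' Measures lumen and wall pixel areas and contour perimeters, converts to
#' micrometres via the pixel scale, and derives the area-based inner and
#' outer equivalent radii, the ring mean thickness (outer minus inner), the
#' perimeter-based radii and the luminal hydraulic diameter.  The
#' area-based radius is the primary estimate; the alternatives are always
#' reported alongside.
#'
#' @param masks a [layer_masks()] object (or any list with logical `lumen`
#'   and `wall` matrices).
#' @param pixel_scale_um_per_px micrometres per pixel.
#' @return object of class `geometry_summary`: a list with
#'   `inner_radius_um`, `outer_radius_um`, `mean_thickness_ring_um`,
#'   `lumen_area_um2`, `wall_area_um2`, `lumen_perimeter_um`,
#'   `outer_perimeter_um`, `inner_radius_perimeter_um`,
#'   `outer_radius_perimeter_um`, `hydraulic_diameter_um`.
#' @export
ring_geometry <- function(masks, pixel_scale_um_per_px) {
  s <- pixel_scale_um_per_px
  stopifnot(s > 0)
  lumen_px <- sum(masks$lumen)
  wall_px <- sum(masks$wall)
  if (wall_px == 0L) stop("degenerate input: empty wall mask")
  A_in <- lumen_px * s^2
  A_out <- (lumen_px + wall_px) * s^2
  P_in <- chain_perimeter_px(masks$lumen) * s
  P_out <- chain_perimeter_px(masks$lumen | masks$wall) * s
  r_in <- equivalent_radius_from_area(A_in)
  r_out <- equivalent_radius_from_area(A_out)
  structure(list(
    inner_radius_um = r_in,
    outer_radius_um = r_out,
    mean_thickness_ring_um = r_out - r_in,
    lumen_area_um2 = A_in,
    wall_area_um2 = wall_px * s^2,
    lumen_perimeter_um = P_in,
    outer_perimeter_um = P_out,
    inner_radius_perimeter_um = radius_from_perimeter(P_in),
    outer_radius_perimeter_um = radius_from_perimeter(P_out),
    hydraulic_diameter_um = if (P_in > 0) hydraulic_diameter(A_in, P_in)
                            else NA_real_
  ), class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("<geometry_summary>\n",
      sprintf("  r_in %.2f um, r_out %.2f um, ring thickness %.2f um\n",
              x$inner_radius_um, x$outer_radius_um,
              x$mean_thickness_ring_um),
      sprintf("  D_h %.2f um; perimeter-based r_in %.2f, r_out %.2f um\n",
              x$hydraulic_diameter_um, x$inner_radius_perimeter_um,
              x$outer_radius_perimeter_um), sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.geometry_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Mean thickness of a transmural strip
#'
#' For a wall strip of image width m, the mean thickness is the sum over
#' columns of the per-column wall pixel count divided by m — identically
#' the total wall pixel area divided by the image width.  Both forms are
#' computed and must agree exactly (they are the same sum); the result is
#' scaled to micrometres.
#'
#' @param strip_mask logical matrix, x = circumferential (width),
#'   y = radial.
#' @param pixel_scale_um_per_px micrometres per pixel.
#' @return mean thickness in um.
#' @export
transmural_mean_thickness <- function(strip_mask, pixel_scale_um_per_px = 1) {
  m <- nrow(strip_mask)                 # image width (columns of the strip)
  if (m == 0L) stop("contract violation: zero image width")
  if (!any(strip_mask)) stop("degenerate input: empty strip mask")
  per_column <- rowSums(strip_mask)     # n_i^Wall at each pixel i along x
  t_sum <- sum(per_column) / m
  t_area <- sum(strip_mask) / m
  stopifnot(isTRUE(all.equal(t_sum, t_area)))  # identity of the two routes
  t_sum * pixel_scale_um_per_px
}

#' Per-layer thicknesses from transmural strip masks
#'
#' Media and adventitia thicknesses are measured by
#' [transmural_mean_thickness()] on their masks; the intimal thickness is
#' obtained by subtracting both from the total wall thickness.  A slightly
#' negative subtraction result (independently measured layers) is clipped
#' to 0 with a warning; a discrepancy beyond `tolerance_um` is an error.
#'
#' @param masks a [layer_masks()] object in strip orientation.
#' @param pixel_scale_um_per_px micrometres per pixel.
#' @param tolerance_um allowed negative intima before erroring (default:
#'   2 pixels worth).
#' @return named numeric: intima, media, adventitia, total (um).
#' @export
layer_thicknesses <- function(masks, pixel_scale_um_per_px = 1,
                              tolerance_um = 2 * pixel_scale_um_per_px) {
  s <- pixel_scale_um_per_px
  total <- transmural_mean_thickness(masks$wall, s)
  t_med <- if (any(masks$media))
    transmural_mean_thickness(masks$media, s) else 0
  t_adv <- if (any(masks$adventitia))
    transmural_mean_thickness(masks$adventitia, s) else 0
  t_int <- total - t_med - t_adv
  if (t_int < -tolerance_um)
    stop("inconsistency error: media + adventitia exceed total thickness ",
         "by more than the tolerance")
  if (t_int < 0) {
    warning("negative intimal thickness clipped to 0")
    t_int <- 0
  }
  c(intima = t_int, media = t_med, adventitia = t_adv, total = total)
}

#' Per-layer thicknesses from whole-ring masks
#'
#' Ring-route analogue of [layer_thicknesses()]: successive equivalent
#' radii of lumen, lumen+intima, +media, +adventitia; each layer thickness
#' is the difference of consecutive radii.
#'
#' @param masks a [layer_masks()] object in ring orientation.
#' @param pixel_scale_um_per_px micrometres per pixel.
#' @return named numeric: intima, media, adventitia, total (um).
#' @export
layer_ring_thicknesses <- function(masks, pixel_scale_um_per_px = 1) {
  s <- pixel_scale_um_per_px
  a0 <- sum(masks$lumen)
  a1 <- a0 + sum(masks$intima)
  a2 <- a1 + sum(masks$media)
  a3 <- a2 + sum(masks$adventitia)
  r <- equivalent_radius_from_area(c(a0, a1, a2, a3) * s^2)
  c(intima = r[2] - r[1], media = r[3] - r[2], adventitia = r[4] - r[3],
    total = r[4] - r[1])
}
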