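## Lumen detection, perivascular cropping and region refinement — the mask
## layer every quantification consumes.

#' Detect the lumen by seeded flood fill
#'
#' Re-implementation of the interactive magic-wand step as a seeded,
#' 4-connected flood fill: the detected region is the connected set of
#' pixels whose intensity differs from the seed pixel's by at most
#' `tolerance`.  If the region exceeds `max_area_frac` of the frame it is
#' treated as a leak (seed placed on wall tissue) and an error is raised.
#' The returned raster honours the lumen-filled-black convention.
#'
#' @param channel numeric matrix, 8-bit intensities.
#' @param seed_point integer c(x, y) inside the lumen (1-based pixel
#'   indices).
#' @param tolerance intensity tolerance in \[0, 255\].
#' @param max_area_frac leak cap as a fraction of the frame (default 0.5).
#' @return list with `mask` (logical lumen mask) and `filled` (the input
#'   channel with the lumen set to 0).
#' @export
detect_lumen <- function(channel, seed_point, tolerance = 10,
                         max_area_frac = 0.5) {
  stopifnot(tolerance >= 0, tolerance <= 255)
  seed_val <- channel[seed_point[1], seed_point[2]]
  candidate <- abs(channel - seed_val) <= tolerance
  mask <- flood_select(candidate, seed_point)
  if (sum(mask) > max_area_frac * length(channel))
    stop("leak error: flood fill exceeded ", max_area_frac,
         " of the frame; seed likely on wall tissue")
  filled <- channel
  filled[mask] <- 0
  list(mask = mask, filled = filled)
}

#' Crop perivascular tissue outside an adventitial contour
#'
#' Removes myocardium/connective tissue outside a closed adventitial
#' contour: pixels outside the polygon are excluded and set to white (255)
#' in the returned raster, and the wall mask is the polygon interior minus
#' the lumen.
#'
#' @param channel numeric matrix (used for the white-filled output).
#' @param adventitial_contour k x 2 matrix of polygon vertices in 0-based
#'   pixel coordinates (x right, y down); must be closed, i.e. first
#'   vertex equal to last.
#' @param lumen_mask logical lumen mask.
#' @return list with `wall` (logical wall mask, flagged empty via
#'   attribute `empty`), `inside` (polygon-interior mask) and `filled`
#'   (channel with the exterior set to 255).
#' @export
crop_perivascular <- function(channel, adventitial_contour, lumen_mask) {
  stopifnot(is.matrix(adventitial_contour),
            ncol(adventitial_contour) == 2L)
  k <- nrow(adventitial_contour)
  if (k < 4L || !all(adventitial_contour[1, ] == adventitial_contour[k, ]))
    stop("contour error: adventitial contour must be a closed polygon ",
         "(first vertex repeated last)")
  inside <- polygon_mask(adventitial_contour, dim(channel))
  wall <- inside & !lumen_mask
  if (!any(wall))
    warning("empty wall mask: contour encloses no tissue outside the lumen")
  attr(wall, "empty") <- !any(wall)
  filled <- channel
  filled[!inside] <- 255
  list(wall = wall, inside = inside, filled = filled)
}

#' Threshold a channel and refine with a median filter
#'
#' Binary mask of pixels at or above `threshold`, then median-filtered with
#' radius `median_radius` to remove small particles; radius 0 is a no-op.
#'
#' @param channel numeric matrix.
#' @param threshold intensity in \[0, 255\].
#' @param median_radius filter radius in pixels (>= 0; default 1).
#' @return logical mask.
#' @export
threshold_roi <- function(channel, threshold, median_radius = 1L) {
  stopifnot(threshold >= 0, threshold <= 255, median_radius >= 0)
  mask <- channel >= threshold
  if (median_radius > 0) {
    f <- EBImage::medianFilter(EBImage::Image(mask * 1),
                               size = as.integer(median_radius))
    mask <- EBImage::imageData(f) > 0.5
  }
  mask
}

#' Assemble layer masks from a wall mask and layer annotations
#'
#' Media and adventitia annotations (cropped separately in practice, or
#' taken from phantom ground truth) are validated against the wall mask and
#' the intima is derived by set subtraction.
#'
#' @param wall logical wall mask.
#' @param lumen logical lumen mask.
#' @param media_annotation,adventitia_annotation logical masks, subsets of
#'   `wall`, mutually disjoint; `NULL` means unannotated.
#' @return a [layer_masks()] object.
#' @export
assemble_layer_masks <- function(wall, lumen, media_annotation = NULL,
                                 adventitia_annotation = NULL) {
  if (!is.null(media_annotation) && any(media_annotation & !wall))
    stop("media annotation extends outside the wall mask")
  if (!is.null(adventitia_annotation) && any(adventitia_annotation & !wall))
    stop("adventitia annotation extends outside the wall mask")
  layer_masks(lumen, wall, media_annotation, adventitia_annotation)
}

#' Extract the outer adventitial contour of a wall mask as a closed polygon
#'
#' Convenience hand-off from phantom ground truth (or any mask) to
#' [crop_perivascular()]: the 8-connected outer boundary of lumen + wall,
#' ordered, in 0-based pixel coordinates, closed.
#'
#' @param masks a [layer_masks()] object.
#' @return k x 2 matrix of vertices with first row repeated last.
#' @export
outer_contour <- function(masks) {
  region <- (masks$lumen | masks$wall) * 1
  oc <- EBImage::ocontour(EBImage::Image(region))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  rbind(pts, pts[1, , drop = FALSE])
}
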