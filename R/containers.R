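#' Multi-channel artery image set
#'
#' Container for a registered multi-channel raster of one arterial
#' cross-section: a named list of 8-bit channels (numeric matrices, all the
#' same dimension, x right / y down), the pixel scale, a batch key
#' (objective, stain) used for per-batch threshold calibration, and an
#' optional matched negative control.
#'
#' @param channels named list of numeric matrices in \[0, 255\], identical
#'   dimensions.
#' @param pixel_scale_um_per_px micrometres per pixel (> 0).
#' @param batch_key character vector `c(objective, stain)`.
#' @param negative_control optional `artery_image_set` of the matched
#'   negative control.
#' @return an object of class `artery_image_set`.
#' @export
artery_image_set <- function(channels, pixel_scale_um_per_px,
                             batch_key = c("unknown", "unknown"),
                             negative_control = NULL) {
  stopifnot(is.list(channels), length(channels) > 0L,
            !is.null(names(channels)))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share dimensions")
  if (pixel_scale_um_per_px <= 0) stop("pixel scale must be positive")
  structure(list(
    channels = channels,
    pixel_scale_um_per_px = as.numeric(pixel_scale_um_per_px),
    batch_key = as.character(batch_key),
    negative_control = negative_control
  ), class = "artery_image_set")
}

#' @export
print.artery_image_set <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<artery_image_set> ", d[1], "x", d[2], " px, ",
      length(x$channels), " channels (",
      paste(names(x$channels), collapse = ", "), ")\n",
      "  scale: ", x$pixel_scale_um_per_px, " um/px; batch: ",
      paste(x$batch_key, collapse = "/"),
      if (!is.null(x$negative_control)) "; has negative control" else "",
      "\n", sep = "")
  invisible(x)
}

#' Lumen, wall and layer masks
#'
#' Boolean rasters for the lumen, the whole wall and the medial and
#' adventitial layers; the intima is derived by set subtraction
#' (wall minus media minus adventitia).  Enforces the mask invariants:
#' lumen and wall disjoint, media and adventitia disjoint subsets of wall.
#'
#' @param lumen,wall,media,adventitia logical matrices of identical
#'   dimension.  `media` and `adventitia` may be `NULL` (no layer
#'   annotation), in which case the intima equals the wall.
#' @return an object of class `layer_masks` with elements `lumen`, `wall`,
#'   `media`, `adventitia`, `intima`.
#' @export
layer_masks <- function(lumen, wall, media = NULL, adventitia = NULL) {
  stopifnot(is.matrix(lumen), is.matrix(wall),
            all(dim(lumen) == dim(wall)))
  if (is.null(media)) media <- matrix(FALSE, nrow(wall), ncol(wall))
  if (is.null(adventitia)) adventitia <- matrix(FALSE, nrow(wall), ncol(wall))
  stopifnot(all(dim(media) == dim(wall)),
            all(dim(adventitia) == dim(wall)))
  if (any(lumen & wall)) stop("lumen and wall masks must be disjoint")
  if (any(media & !wall)) stop("media annotation must lie inside the wall")
  if (any(adventitia & !wall)) stop("adventitia annotation must lie inside the wall")
  if (any(media & adventitia)) stop("media and adventitia annotations overlap")
  structure(list(
    lumen = lumen, wall = wall, media = media, adventitia = adventitia,
    intima = wall & !media & !adventitia
  ), class = "layer_masks")
}

#' @export
print.layer_masks <- function(x, ...) {
  cat("<layer_masks> ", nrow(x$wall), "x", ncol(x$wall), " px\n",
      "  areas (px): lumen ", sum(x$lumen), ", wall ", sum(x$wall),
      " (intima ", sum(x$intima), ", media ", sum(x$media),
      ", adventitia ", sum(x$adventitia), ")\n", sep = "")
  invisible(x)
}
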