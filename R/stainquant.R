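## Constituent area-fraction quantification: negative-control-calibrated
## fluorescence thresholds, VVG elastin with nuclei-blob removal, and PSR
## brightfield/polarized collagen.

#' Calibrate a positivity threshold against a negative control
#'
#' Both intensity sets are histogrammed on the 8-bit range and normalized
#' to unit mass (sample and control wall masks differ in pixel count); the
#' per-bin difference (sample minus control) is computed, and the threshold
#' is the minimum intensity of the highest-intensity contiguous run of
#' bins where the difference is non-negative and that contains at least
#' one strictly positive bin — the low tail of the sample-specific signal
#' mode.  Zero-difference bins (no mass in either histogram) do not break
#' the run, which makes the rule robust to the sparse, gappy signal
#' histograms of small masks; the reported threshold is the lowest bin
#' inside the run whose difference is strictly positive.  If no bin is
#' positive anywhere the sentinel 256 is returned with `flagged = TRUE`,
#' meaning "nothing positive".
#'
#' @param sample_values intensities of the sample channel within its wall
#'   mask.
#' @param control_values intensities of the matched negative control within
#'   its wall mask.
#' @param channel which colour channel the intensities came from
#'   (bookkeeping only).
#' @param batch_key (objective, stain) batch the calibration applies to.
#' @return object of class `threshold_calibration`: list with `threshold`
#'   (0-255, or 256 sentinel), `flagged`, `channel`, `batch_key`,
#'   `control_histogram`, `sample_histogram`.
#' @export
calibrate_threshold <- function(sample_values, control_values,
                                channel = "green",
                                batch_key = c("unknown", "unknown")) {
  if (length(sample_values) == 0L || length(control_values) == 0L)
    stop("degenerate input: empty sample or control mask")
  hs <- hist256(sample_values)
  hc <- hist256(control_values)
  diff_raw <- hs / sum(hs) - hc / sum(hc)
  if (!any(diff_raw > 0)) {
    thr <- 256L; flagged <- TRUE
  } else {
    nonneg <- diff_raw >= 0
    runs <- rle(nonneg)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    has_pos <- vapply(seq_along(runs$values), function(k) {
      runs$values[k] && any(diff_raw[starts[k]:ends[k]] > 0)
    }, logical(1))
    run_bins <- starts[max(which(has_pos))]:ends[max(which(has_pos))]
    thr_bin <- min(run_bins[diff_raw[run_bins] > 0])
    thr <- as.integer(min(max(thr_bin - 1L, 0L), 255L))  # bin i = intensity i-1
    flagged <- FALSE
  }
  structure(list(threshold = thr, flagged = flagged, channel = channel,
                 batch_key = as.character(batch_key),
                 sample_histogram = hs, control_histogram = hc),
            class = "threshold_calibration")
}

new_stain_fraction <- function(stain, positive, wall, threshold,
                               extra = list()) {
  structure(c(list(
    stain = stain,
    fraction = positive / wall,
    positive_pixels = as.integer(positive),
    wall_pixels = as.integer(wall),
    threshold = threshold
  ), extra), class = "stain_fraction_record")
}

#' @export
print.stain_fraction_record <- function(x, ...) {
  cat(sprintf("<stain_fraction> %s: %.4f (%d / %d px, threshold %s)\n",
              x$stain, x$fraction, x$positive_pixels, x$wall_pixels,
              format(x$threshold)), sep = "")
  invisible(x)
}

#' Positive-stain area fraction of the wall
#'
#' Fraction of wall pixels at or above the threshold.  The sentinel
#' threshold 256 (nothing positive, see [calibrate_threshold()]) yields
#' fraction 0.
#'
#' @param channel numeric matrix.
#' @param wall_mask logical wall mask (non-empty).
#' @param threshold intensity in \[0, 256\].
#' @param stain stain name for the record.
#' @return a `stain_fraction_record`.
#' @export
area_fraction <- function(channel, wall_mask, threshold, stain = "stain") {
  stopifnot(threshold >= 0, threshold <= 256)
  wall_px <- sum(wall_mask)
  if (wall_px == 0L) stop("degenerate input: empty wall mask")
  positive <- sum(channel[wall_mask] >= threshold)
  new_stain_fraction(stain, positive, wall_px, threshold)
}

#' Elastin area fraction from a VVG-like image with nuclei-blob removal
#'
#' Elastin renders dark under VVG, but so do nuclei: dark pixels within the
#' wall are labelled into connected components, and components smaller than
#' `min_blob_size` that are also compact (circularity >= `min_circularity`)
#' are classified as nuclei and removed before the fraction is computed.
#' The compactness test protects thin elastin fragments, which are small
#' but elongated.
#'
#' @param vvg_channel numeric matrix (dark = elastin-like).
#' @param wall_mask logical wall mask.
#' @param elastin_threshold intensities <= this count as dark (default
#'   128).
#' @param min_blob_size blob area in pixels below which a compact component
#'   is removed as a nucleus (0 = no removal).
#' @param min_circularity circularity (4 pi A / P^2) at or above which a
#'   small component counts as compact (default 0.5).
#' @return a `stain_fraction_record` with extra fields `min_blob_size` and
#'   `removed_blobs`.
#' @export
elastin_fraction_vvg <- function(vvg_channel, wall_mask,
                                 elastin_threshold = 128,
                                 min_blob_size = 50L,
                                 min_circularity = 0.5) {
  stopifnot(min_blob_size >= 0)
  wall_px <- sum(wall_mask)
  if (wall_px == 0L) stop("degenerate input: empty wall mask")
  dark <- (vvg_channel <= elastin_threshold) & wall_mask
  removed <- 0L
  if (min_blob_size > 0 && any(dark)) {
    lab <- EBImage::bwlabel(EBImage::Image(dark * 1))
    shp <- EBImage::computeFeatures.shape(lab)
    if (!is.null(shp) && nrow(shp) > 0) {
      area <- shp[, "s.area"]
      per <- pmax(shp[, "s.perimeter"], 1)
      circ <- 4 * pi * area / per^2
      drop_ids <- which(area < min_blob_size & circ >= min_circularity)
      if (length(drop_ids)) {
        labdat <- EBImage::imageData(lab)
        dark[labdat %in% drop_ids] <- FALSE
        removed <- length(drop_ids)
      }
    }
  }
  new_stain_fraction("elastin", sum(dark), wall_px, elastin_threshold,
                     extra = list(min_blob_size = min_blob_size,
                                  removed_blobs = removed))
}

#' Collagen area fraction from a PSR brightfield/polarized pair
#'
#' The region of interest is the set of red-dominant wall pixels in the
#' non-polarized brightfield (red exceeding green and blue by
#' `red_margin`); collagen-positive pixels are ROI pixels whose polarized
#' intensity exceeds `black_threshold` (birefringence).  The fraction is
#' positives over total wall pixels.
#'
#' @param brightfield named list of `red`, `green`, `blue` matrices.
#' @param polarized numeric matrix, registered to the brightfield.
#' @param wall_mask logical wall mask.
#' @param red_margin red-dominance margin (default 20).
#' @param black_threshold polarized intensity above which a pixel is "not
#'   black" (default 50).
#' @return a `stain_fraction_record` with extra fields `black_threshold`
#'   and `roi_pixels`.
#' @export
collagen_fraction_psr <- function(brightfield, polarized, wall_mask,
                                  red_margin = 20, black_threshold = 50) {
  stopifnot(all(c("red", "green", "blue") %in% names(brightfield)),
            black_threshold >= 0, black_threshold <= 255)
  if (!all(dim(brightfield$red) == dim(polarized)) ||
      !all(dim(polarized) == dim(wall_mask)))
    stop("registration error: image dimensions differ")
  wall_px <- sum(wall_mask)
  if (wall_px == 0L) stop("degenerate input: empty wall mask")
  roi <- wall_mask &
    (brightfield$red > brightfield$green + red_margin) &
    (brightfield$red > brightfield$blue + red_margin)
  positive <- roi & (polarized > black_threshold)
  rec <- new_stain_fraction("collagen", sum(positive), wall_px,
                            black_threshold,
                            extra = list(black_threshold = black_threshold,
                                         roi_pixels = sum(roi)))
  rec$stain <- "collagen"
  rec
}

#' Batch stain quantification over image sets
#'
#' Applies one calibration per (objective, stain) batch key to every image
#' set, yielding one fraction record per (image, stain) in a deterministic
#' (sorted) long-format table.
#'
#' @param image_sets named list of [artery_image_set()]s.
#' @param wall_masks named list of logical wall masks, same names.
#' @param calibrations named list of `threshold_calibration`s keyed
#'   `"<objective>_<stain>"` where stain is the channel name.
#' @param stains channel names to quantify.
#' @return tibble with columns image, stain, fraction, positive_pixels,
#'   wall_pixels, threshold, sorted by (image, stain).
#' @export
batch_quantify <- function(image_sets, wall_masks, calibrations,
                           stains = c("sma", "cd34", "mac387")) {
  stopifnot(length(image_sets) > 0L,
            setequal(names(image_sets), names(wall_masks)))
  rows <- list()
  for (nm in names(image_sets)) {
    img <- image_sets[[nm]]
    for (st in stains) {
      key <- paste(img$batch_key[1], st, sep = "_")
      cal <- calibrations[[key]]
      if (is.null(cal))
        stop("lookup error: no calibration for batch key ", key)
      rec <- area_fraction(img$channels[[st]], wall_masks[[nm]],
                           cal$threshold, stain = st)
      rows[[paste(nm, st)]] <- tibble::tibble(
        image = nm, stain = st, fraction = rec$fraction,
        positive_pixels = rec$positive_pixels,
        wall_pixels = rec$wall_pixels, threshold = rec$threshold)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$image, .data$stain)
}
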