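## Nuclei centroid detection, normalized transmural wall positions, the
## 25 x 25 distribution grid and cell densities.

#' Detect nuclei centroids
#'
#' Connected components of pixels at or above `min_intensity` with area at
#' least `min_size` are taken as nuclei; the centroid of each is the
#' intensity-weighted mean pixel position.  Centroids closer than
#' `min_separation` are merged (single-link) into one, the merged centroid
#' being the intensity-weighted mean of the members.
#'
#' @param channel numeric matrix (nuclei bright).
#' @param min_size minimum component area in pixels.
#' @param min_separation minimum centroid separation in pixels.
#' @param min_intensity positivity threshold.
#' @return n x 2 matrix of (x, y) centroids (possibly 0-row).
#' @export
detect_nuclei <- function(channel, min_size = 4L, min_separation = 4,
                          min_intensity = 120) {
  stopifnot(min_size >= 0, min_separation >= 0, min_intensity >= 0)
  fg <- channel >= min_intensity
  if (!any(fg)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  ids <- sort(unique(lab[lab > 0]))
  cents <- t(vapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE, useNames = FALSE)
    if (nrow(idx) < min_size) return(c(NA_real_, NA_real_, 0))
    w <- channel[idx]
    c(sum(idx[, 1] * w) / sum(w), sum(idx[, 2] * w) / sum(w), sum(w))
  }, numeric(3)))
  cents <- cents[!is.na(cents[, 1]), , drop = FALSE]
  if (nrow(cents) == 0L) return(matrix(numeric(0), 0, 2))
  if (min_separation > 0 && nrow(cents) > 1L) {
    hc <- stats::hclust(stats::dist(cents[, 1:2]), method = "single")
    grp <- stats::cutree(hc, h = min_separation - .Machine$double.eps)
    cents <- t(vapply(unique(grp), function(g) {
      sub <- cents[grp == g, , drop = FALSE]
      w <- sub[, 3]
      c(sum(sub[, 1] * w) / sum(w), sum(sub[, 2] * w) / sum(w), sum(w))
    }, numeric(3)))
  }
  cents[, 1:2, drop = FALSE]
}

#' Normalized transmural wall position of centroids
#'
#' Position = d_L / (d_L + d_A), where d_L and d_A are the Euclidean
#' distances from the centroid to the nearest lumen-border pixel and to
#' the nearest outer adventitial-border pixel: 0 on the luminal border,
#' 1 on the outer border.  Borders are the 4-connected inner border of the
#' lumen mask and the outer border of lumen + wall.
#'
#' @param centroids n x 2 matrix of (x, y) positions; every centroid must
#'   lie inside the wall mask.
#' @param masks a [layer_masks()] object.
#' @return numeric vector of positions in \[0, 1\].
#' @export
wall_position <- function(centroids, masks) {
  if (nrow(centroids) == 0L) return(numeric(0))
  px <- pmin(pmax(round(centroids[, 1]), 1), nrow(masks$wall))
  py <- pmin(pmax(round(centroids[, 2]), 1), ncol(masks$wall))
  inside <- masks$wall[cbind(px, py)]
  if (!all(inside))
    stop("contract violation: centroid outside the wall mask")
  lum_b <- mask_coords(mask_border(masks$lumen))
  out_b <- mask_coords(mask_border(masks$lumen | masks$wall))
  dL <- nearest_dist(centroids, lum_b)
  dA <- nearest_dist(centroids, out_b)
  dL / (dL + dA)
}

#' 25 x 25 nuclei distribution grid
#'
#' Bins centroids into `n_bins` transmural segments (normalized wall
#' position) by `n_bins` circumferential segments (angular position around
#' the lumen centroid mapped to \[0, 1)), with half-open bins, last bin
#' closed.  The normalized grid divides all counts by the largest single
#' bin count along the transmural direction (so its maximum is exactly 1
#' whenever any nucleus exists); `normalize = "column"` instead normalizes
#' each circumferential column by its own transmural maximum.
#'
#' @param wall_positions transmural positions in \[0, 1\]
#'   (see [wall_position()]).
#' @param circ_positions circumferential positions in \[0, 1\]; see
#'   [circumferential_position()].
#' @param n_bins grid size per direction (default 25).
#' @param normalize `"global"` (default) or `"column"`.
#' @return object of class `nuclei_grid`: list with `grid` (transmural x
#'   circumferential counts), `normalized_grid`, `transmural_profile`
#'   (row sums), `count`.
#' @export
radial_grid <- function(wall_positions, circ_positions, n_bins = 25L,
                        normalize = c("global", "column")) {
  normalize <- match.arg(normalize)
  stopifnot(length(wall_positions) == length(circ_positions),
            all(wall_positions >= 0 & wall_positions <= 1),
            all(circ_positions >= 0 & circ_positions <= 1))
  bin_of <- function(u) pmin(floor(u * n_bins) + 1L, n_bins)
  g <- matrix(0L, n_bins, n_bins)
  if (length(wall_positions)) {
    ti <- bin_of(wall_positions)
    ci <- bin_of(circ_positions)
    for (k in seq_along(ti)) g[ti[k], ci[k]] <- g[ti[k], ci[k]] + 1L
  }
  norm <- matrix(0, n_bins, n_bins)
  if (sum(g) > 0) {
    if (normalize == "global") {
      norm <- g / max(g)
    } else {
      for (j in seq_len(n_bins)) {
        mj <- max(g[, j])
        if (mj > 0) norm[, j] <- g[, j] / mj
      }
    }
  }
  structure(list(grid = g, normalized_grid = norm,
                 transmural_profile = rowSums(g),
                 count = sum(g), n_bins = n_bins,
                 normalize = normalize),
            class = "nuclei_grid")
}

#' Circumferential position of centroids around the lumen centroid
#'
#' Angle of each centroid about the lumen mask centroid, mapped linearly
#' from (-pi, pi\] to \[0, 1).
#'
#' @param centroids n x 2 matrix.
#' @param lumen_mask logical lumen mask.
#' @return numeric vector in \[0, 1).
#' @export
circumferential_position <- function(centroids, lumen_mask) {
  if (nrow(centroids) == 0L) return(numeric(0))
  cc <- colMeans(mask_coords(lumen_mask))
  th <- atan2(centroids[, 2] - cc[2], centroids[, 1] - cc[1])
  u <- (th + pi) / (2 * pi)
  u[u >= 1] <- 0
  u
}

#' Cell density
#'
#' Centroid count divided by wall area.
#' @param count nuclei count (>= 0).
#' @param wall_area_um2 wall area in square micrometres (> 0).
#' @return density in cells per square micrometre.
#' @export
cell_density <- function(count, wall_area_um2) {
  if (wall_area_um2 <= 0) stop("contract violation: wall area must be positive")
  count / wall_area_um2
}
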