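## Synthetic artery-phantom rendering.
##
## Geometry model: the lumen is an area-preserving ellipse (semi-axes
## r(1+e), r/(1+e), so lumen area is pi r^2 for every eccentricity e) and
## each wall layer is a constant-thickness offset band of the lumen,
## obtained from the Euclidean distance transform of the lumen region.
## Layer thicknesses are therefore exact by construction, and the analytic
## outer equivalent radius follows from the parallel-curve area formula
## A_out = A_in + P_in * T + pi * T^2.

BG_FLUOR <- 40    # nonzero background (models residual autofluorescence)
SIG_FLUOR <- 180  # positive-stain intensity (signal:background 4.5)
VVG_WALL <- 200   # bright wall tissue in the VVG-like channel
VVG_ELASTIN <- 30 # elastin renders near-black under VVG
VVG_NUCLEUS <- 40 # nuclei also take up the stain (must be removed later)
DAPI_NUCLEUS <- 200
NUCLEUS_R_PX <- 2 # nucleus blob radius

## Ramanujan's second approximation to the ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

## Rasterize lumen + offset layers; shared by all phantom flavours.
phantom_geometry <- function(spec, dim = NULL, margin_px = 8L) {
  scale <- spec$pixel_scale_um_per_px
  r_px <- spec$inner_radius_um / scale
  t_px <- spec$layer_thicknesses_um / scale
  T_px <- sum(t_px)
  a <- r_px * (1 + spec$eccentricity)
  b <- r_px / (1 + spec$eccentricity)
  nx_need <- ceiling(2 * (a + T_px)) + 2L * margin_px
  ny_need <- ceiling(2 * (b + T_px)) + 2L * margin_px
  if (is.null(dim)) {
    nx <- nx_need; ny <- ny_need
  } else {
    nx <- dim[1]; ny <- dim[2]
    if (nx < nx_need || ny < ny_need)
      stop("sizing error: lumen plus layer thicknesses exceed the image bounds (need ",
           nx_need, "x", ny_need, " px)")
  }
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- matrix(rep(seq_len(nx), times = ny), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  lumen <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  dmap <- EBImage::imageData(EBImage::distmap(EBImage::Image((!lumen) * 1)))
  wall <- dmap > 0 & dmap <= T_px
  intima <- dmap > 0 & dmap <= t_px[1]
  media <- dmap > t_px[1] & dmap <= t_px[1] + t_px[2]
  adventitia <- dmap > t_px[1] + t_px[2] & dmap <= T_px
  list(lumen = lumen, wall = wall, intima = intima, media = media,
       adventitia = adventitia, dmap = dmap,
       center = c(cx, cy), axes = c(a, b),
       t_px = t_px, T_px = T_px, dim = c(nx, ny))
}

## Pick the exact painted set for a diffuse constituent: a uniform random
## subset of wall pixels of size round(fraction * wall pixels).
paint_diffuse <- function(wall_idx, fraction) {
  target <- round(fraction * length(wall_idx))
  if (target == 0L) return(integer(0))
  sample(wall_idx, target)
}

## Elastin painted as n_lamellae thin rings across the media, widened until
## the band holds at least the target count, then randomly trimmed to the
## exact count (never padded with isolated pixels, so blob removal cannot
## eat legitimate elastin).
paint_lamellae <- function(geom, wall_idx, fraction, n_lamellae) {
  target <- round(fraction * length(wall_idx))
  if (target == 0L) return(integer(0))
  t1 <- geom$t_px[1]; t2 <- geom$t_px[2]
  centers <- t1 + (seq_len(n_lamellae) - 0.5) * t2 / n_lamellae
  d_wall <- geom$dmap[wall_idx]
  band_dist <- do.call(pmin, lapply(centers, function(cc) abs(d_wall - cc)))
  ## paint the sublevel set of the distance to the nearest lamella
  ## centerline: every pixel at least as close as the target-th closest.
  ## The painted set is a union of contiguous rings (never fragmented, so
  ## later blob removal cannot misclassify elastin as nuclei); including
  ## cutoff ties may overshoot the requested count by a sliver of a shell,
  ## and the ground truth records the actual painted fraction.
  ## a band narrower than ~1.5 px fragments on the raster, so the cutoff
  ## never drops below 0.75 px even when that overshoots the target count
  cutoff <- max(sort(band_dist, partial = target)[target], 0.75)
  wall_idx[band_dist <= cutoff]
}

## Dart-throwing placement of non-overlapping nucleus blobs wholly inside
## the wall and clear of painted elastin.
place_nuclei <- function(geom, elastin_idx, count,
                         r_blob = NUCLEUS_R_PX, sep = 2 * NUCLEUS_R_PX + 2) {
  if (count == 0L) return(matrix(numeric(0), 0, 2))
  nx <- geom$dim[1]; ny <- geom$dim[2]
  inside <- geom$wall &
    EBImage::imageData(EBImage::distmap(EBImage::Image(geom$wall * 1))) >
      (r_blob + 0.5)
  if (length(elastin_idx) > 0L) {
    el <- matrix(FALSE, nx, ny); el[elastin_idx] <- TRUE
    d_el <- EBImage::imageData(EBImage::distmap(EBImage::Image((!el) * 1)))
    inside <- inside & d_el > (r_blob + 2)
  }
  cand <- mask_coords(inside)
  if (nrow(cand) == 0L)
    stop("overlap-budget error: no room for any nucleus in the wall")
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  accepted <- matrix(numeric(0), 0, 2)
  sep2 <- sep^2
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(accepted) > 0L) {
      d2 <- (accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2
      if (min(d2) < sep2) next
    }
    accepted <- rbind(accepted, p)
    if (nrow(accepted) == count) break
  }
  if (nrow(accepted) < count)
    stop("overlap-budget error: requested nuclei density unachievable ",
         "without overlap (placed ", nrow(accepted), " of ", count, ")")
  accepted
}

## indices of the disc of radius r around each centre (clipped to image)
disc_indices <- function(centers, r, dim) {
  if (nrow(centers) == 0L) return(integer(0))
  off <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  idx <- integer(0)
  for (i in seq_len(nrow(centers))) {
    x <- centers[i, 1] + off$dx; y <- centers[i, 2] + off$dy
    ok <- x >= 1 & x <= dim[1] & y >= 1 & y <= dim[2]
    idx <- c(idx, (y[ok] - 1) * dim[1] + x[ok])
  }
  unique(idx)
}

add_noise <- function(channel, sd) {
  if (sd <= 0) return(quantize8(channel))
  quantize8(channel + stats::rnorm(length(channel), 0, sd))
}

## true wall positions of nuclei: normalized nearest-border distance
## d_L / (d_L + d_A), with borders taken as the 4-connected inner border of
## the lumen and the outer (abluminal) border of the wall.
true_wall_positions <- function(centers, geom) {
  if (nrow(centers) == 0L) return(numeric(0))
  lum_b <- mask_coords(mask_border(geom$lumen))
  out_b <- mask_coords(mask_border(geom$lumen | geom$wall))
  dL <- nearest_dist(centers, lum_b)
  dA <- nearest_dist(centers, out_b)
  dL / (dL + dA)
}

#' Render a synthetic artery phantom with exact ground truth
#'
#' Rasterizes one annular artery cross-section at the geometry, composition,
#' nuclei density and noise level fixed by a [phantom_spec()].  The returned
#' image set carries a VVG-like brightfield channel (elastin and nuclei
#' dark, wall bright, lumen filled black, extra-adventitial space white),
#' one fluorescence channel per constituent (`sma`, `cd34`, `mac387`) and a
#' nuclei channel (`dapi`).  Ground truth records the exact painted pixel
#' sets, so constituent fractions equal painted-pixel count divided by
#' wall-pixel count exactly; intensity noise never changes mask membership.
#' Output is bit-identical for a fixed spec (the spec's seed drives all
#' randomness through an isolated RNG).
#'
#' @param spec a [phantom_spec()].
#' @param dim optional c(nx, ny) image size in pixels; by default sized to
#'   fit the vessel plus an 8 px margin.  A `dim` too small for the
#'   requested geometry raises a sizing error.
#' @return a list with elements `images` ([artery_image_set()]), `masks`
#'   ([layer_masks()]) and `truth` — a `ground_truth` list holding analytic
#'   inner/outer equivalent radii (um), true per-layer thicknesses (um),
#'   exact per-channel positive fractions, nuclei centroids with true wall
#'   positions, nuclei count and wall areas.
#' @export
make_artery_phantom <- function(spec, dim = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    geom <- phantom_geometry(spec, dim)
    wall_idx <- which(geom$wall)
    W <- length(wall_idx)
    scale <- spec$pixel_scale_um_per_px
    fr <- spec$constituent_fractions

    elastin_idx <- paint_lamellae(geom, wall_idx, fr[["elastin"]],
                                  spec$n_lamellae)
    sets <- list(
      elastin = elastin_idx,
      sma = paint_diffuse(wall_idx, fr[["sma"]]),
      collagen = paint_diffuse(wall_idx, fr[["collagen"]]),
      cd34 = paint_diffuse(wall_idx, fr[["cd34"]]),
      mac387 = paint_diffuse(wall_idx, fr[["mac387"]])
    )

    wall_area_um2 <- W * scale^2
    n_nuc <- round(spec$nuclei_density_cells_per_um2 * wall_area_um2)
    centers <- place_nuclei(geom, elastin_idx, n_nuc)
    nuc_idx <- disc_indices(centers, NUCLEUS_R_PX, geom$dim)

    base <- matrix(BG_FLUOR, geom$dim[1], geom$dim[2])
    fluor <- function(idx) { ch <- base; ch[idx] <- SIG_FLUOR
                             add_noise(ch, spec$noise_sd) }
    vvg <- matrix(VVG_WALL, geom$dim[1], geom$dim[2])
    vvg[!geom$wall] <- 255          # non-wall filled white
    vvg[elastin_idx] <- VVG_ELASTIN
    vvg[nuc_idx] <- VVG_NUCLEUS
    vvg <- add_noise(vvg, spec$noise_sd)
    vvg[geom$lumen] <- 0            # lumen filled black, noise-free fill
    dapi <- base; dapi[nuc_idx] <- DAPI_NUCLEUS
    channels <- list(
      vvg = vvg,
      sma = fluor(sets$sma),
      cd34 = fluor(sets$cd34),
      mac387 = fluor(sets$mac387),
      dapi = add_noise(dapi, spec$noise_sd)
    )

    images <- artery_image_set(channels, scale,
                               batch_key = c("synthetic", spec$artery_class))
    masks <- layer_masks(geom$lumen, geom$wall, geom$media, geom$adventitia)

    a0 <- geom$axes[1]; b0 <- geom$axes[2]
    A_in <- pi * a0 * b0
    A_out <- A_in + ellipse_perimeter(a0, b0) * geom$T_px + pi * geom$T_px^2
    truth <- structure(list(
      inner_radius_um = sqrt(A_in / pi) * scale,
      outer_radius_um = sqrt(A_out / pi) * scale,
      layer_thickness_um = spec$layer_thicknesses_um,
      mean_thickness_um = sum(spec$layer_thicknesses_um),
      fractions = vapply(sets, function(s) length(s) / W, numeric(1)),
      painted = sets,
      nuclei_centroids = centers,
      nuclei_wall_positions = true_wall_positions(centers, geom),
      nuclei_count = nrow(centers),
      wall_pixels = W,
      lumen_pixels = sum(geom$lumen),
      wall_area_um2 = wall_area_um2,
      pixel_scale_um_per_px = scale
    ), class = "ground_truth")

    list(images = images, masks = masks, truth = truth)
  })
}

#' Render the matched negative control of a phantom
#'
#' Same geometry and noise model as [make_artery_phantom()] but with zero
#' specific stain signal: fluorescence channels carry only the background
#' intensity distribution (mostly-dark image), mirroring primary-antibody
#' substitution with buffer.
#'
#' @inheritParams make_artery_phantom
#' @return an [artery_image_set()] with channels `vvg`, `sma`, `cd34`,
#'   `mac387`, `dapi`.
#' @export
make_negative_control <- function(spec, dim = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed + 104729L, {
    geom <- phantom_geometry(spec, dim)
    base <- matrix(BG_FLUOR, geom$dim[1], geom$dim[2])
    vvg <- matrix(VVG_WALL, geom$dim[1], geom$dim[2])
    vvg[!geom$wall] <- 255
    vvg <- add_noise(vvg, spec$noise_sd)
    vvg[geom$lumen] <- 0
    channels <- list(
      vvg = vvg,
      sma = add_noise(base, spec$noise_sd),
      cd34 = add_noise(base, spec$noise_sd),
      mac387 = add_noise(base, spec$noise_sd),
      dapi = add_noise(base, spec$noise_sd)
    )
    artery_image_set(channels, spec$pixel_scale_um_per_px,
                     batch_key = c("synthetic", spec$artery_class))
  })
}

#' Render a picrosirius-red brightfield/polarized phantom pair
#'
#' The brightfield image is red-dominant exactly on the painted collagen
#' pixels; the polarized image is bright exactly on a ground-truth-recorded
#' birefringent subset of those pixels and near-black elsewhere, emulating
#' collagen birefringence under circularly polarized light.
#'
#' @inheritParams make_artery_phantom
#' @param birefringent_fraction fraction of painted collagen pixels that
#'   light up under polarization (default 1: all fibrillar).
#' @return a list with `brightfield` (named list of `red`, `green`, `blue`
#'   channels), `polarized` (one channel), `masks` and `truth`; the truth
#'   additionally records `birefringent` pixel indices (a subset of the
#'   painted collagen set).
#' @export
make_psr_pair <- function(spec, birefringent_fraction = 1, dim = NULL) {
  stopifnot(inherits(spec, "phantom_spec"),
            birefringent_fraction >= 0, birefringent_fraction <= 1)
  withr::with_seed(spec$seed + 15485863L, {
    geom <- phantom_geometry(spec, dim)
    wall_idx <- which(geom$wall)
    W <- length(wall_idx)
    collagen <- paint_diffuse(wall_idx, spec$constituent_fractions[["collagen"]])
    n_bir <- round(birefringent_fraction * length(collagen))
    birefringent <- if (n_bir >= length(collagen)) collagen
                    else sample(collagen, n_bir)

    gray <- matrix(150, geom$dim[1], geom$dim[2])
    red <- gray; green <- gray; blue <- gray
    red[collagen] <- 200; green[collagen] <- 90; blue[collagen] <- 90
    red[!geom$wall] <- 255; green[!geom$wall] <- 255; blue[!geom$wall] <- 255
    pol <- matrix(10, geom$dim[1], geom$dim[2])
    pol[birefringent] <- 200
    sd <- spec$noise_sd
    brightfield <- list(red = add_noise(red, sd), green = add_noise(green, sd),
                        blue = add_noise(blue, sd))
    polarized <- add_noise(pol, sd)
    masks <- layer_masks(geom$lumen, geom$wall, geom$media, geom$adventitia)
    truth <- list(
      collagen_fraction = length(collagen) / W,
      birefringent_fraction_of_wall = length(birefringent) / W,
      painted_collagen = collagen,
      birefringent = birefringent,
      wall_pixels = W
    )
    list(brightfield = brightfield, polarized = polarized,
         masks = masks, truth = truth)
  })
}

#' Render an unrolled transmural wall strip
#'
#' Emulates the higher-magnification transmural images used to verify the
#' ring thickness measurements: the wall appears as a horizontal band
#' (lumen side up), layers stacked intima/media/adventitia, optionally with
#' a sinusoidal undulation of the luminal boundary.  Ground truth records
#' the per-layer mean column thickness computed from the painted masks.
#'
#' @inheritParams make_artery_phantom
#' @param width_px strip width (circumferential extent) in pixels.
#' @param undulation_px amplitude of the sinusoidal boundary undulation.
#' @return list with `images` (channel `vvg`), `masks` and `truth`
#'   (`layer_thickness_um` as painted, plus exact pixel column means).
#' @export
make_transmural_strip <- function(spec, width_px = 200L, undulation_px = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed + 32452843L, {
    scale <- spec$pixel_scale_um_per_px
    t_px <- spec$layer_thicknesses_um / scale
    T_px <- sum(t_px)
    margin <- 8L
    nx <- as.integer(width_px)
    ny <- as.integer(ceiling(T_px + 2 * undulation_px) + 2L * margin)
    xs <- seq_len(nx)
    top <- margin + undulation_px * (1 + sin(2 * pi * xs / nx))
    ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
    topm <- matrix(rep(top, times = ny), nx, ny)
    depth <- ys - topm                       # signed depth below lumen border
    lumen <- depth <= 0
    wall <- depth > 0 & depth <= T_px
    intima <- depth > 0 & depth <= t_px[1]
    media <- depth > t_px[1] & depth <= t_px[1] + t_px[2]
    adventitia <- depth > t_px[1] + t_px[2] & depth <= T_px
    vvg <- matrix(VVG_WALL, nx, ny)
    vvg[!wall] <- 255
    vvg <- add_noise(vvg, spec$noise_sd)
    vvg[lumen] <- 0
    images <- artery_image_set(list(vvg = vvg), scale,
                               batch_key = c("synthetic_strip",
                                             spec$artery_class))
    masks <- layer_masks(lumen, wall, media, adventitia)
    truth <- list(
      layer_thickness_um = spec$layer_thicknesses_um,
      mean_thickness_um = sum(spec$layer_thicknesses_um),
      column_mean_px = c(intima = sum(intima) / nx, media = sum(media) / nx,
                         adventitia = sum(adventitia) / nx,
                         wall = sum(wall) / nx),
      width_px = nx
    )
    list(images = images, masks = masks, truth = truth)
  })
}
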