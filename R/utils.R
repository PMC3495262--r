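## Internal raster helpers shared across modules.

clamp8 <- function(x) pmin(pmax(x, 0), 255)

## round + clamp to the 8-bit grid
quantize8 <- function(x) round(clamp8(x))

## 256-bin histogram of 8-bit intensities (bin i counts intensity i-1)
hist256 <- function(values) {
  tabulate(as.integer(round(values)) + 1L, nbins = 256L)
}

## coordinates (x, y) of TRUE pixels in a mask, as an n x 2 matrix
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE, useNames = FALSE)
}

## 4-connected inner border of a mask: TRUE pixels with at least one
## 4-neighbour outside the mask (image edge counts as outside)
mask_border <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  padded <- matrix(FALSE, nx + 2L, ny + 2L)
  padded[2:(nx + 1L), 2:(ny + 1L)] <- mask
  core <- padded[2:(nx + 1L), 2:(ny + 1L)]
  up    <- padded[2:(nx + 1L), 1:ny]
  down  <- padded[2:(nx + 1L), 3:(ny + 2L)]
  left  <- padded[1:nx, 2:(ny + 1L)]
  right <- padded[3:(nx + 2L), 2:(ny + 1L)]
  core & !(up & down & left & right)
}

## Seeded 4-connected region growing over a logical candidate raster.
## Vectorized wavefront expansion; returns the component containing seed.
flood_select <- function(candidate, seed) {
  stopifnot(is.matrix(candidate), length(seed) == 2L)
  nx <- nrow(candidate); ny <- ncol(candidate)
  sx <- as.integer(seed[1]); sy <- as.integer(seed[2])
  if (sx < 1L || sx > nx || sy < 1L || sy > ny)
    stop("seed point lies outside the image")
  if (!candidate[sx, sy])
    return(matrix(FALSE, nx, ny))
  region <- matrix(FALSE, nx, ny)
  region[sx, sy] <- TRUE
  frontier <- region
  repeat {
    grown <- shift_or4(frontier)
    newpix <- grown & candidate & !region
    if (!any(newpix)) break
    region <- region | newpix
    frontier <- newpix
  }
  region
}

## union of the four 1-pixel axial shifts of a logical matrix
shift_or4 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  out[-1, ]  <- out[-1, ]  | m[-nx, ]
  out[-nx, ] <- out[-nx, ] | m[-1, ]
  out[, -1]  <- out[, -1]  | m[, -ny]
  out[, -ny] <- out[, -ny] | m[, -1]
  out
}

## Freeman chain-code perimeter of the largest foreground object, with the
## classical corner-corrected step weights (0.948 axial, 1.340 diagonal)
## that remove most of the raster overestimation bias on smooth contours.
chain_perimeter_px <- function(mask) {
  if (!any(mask)) return(0)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) return(0)
  ## sum over all objects' contours
  total <- 0
  for (pts in oc) {
    n <- nrow(pts)
    if (n < 2L) next
    nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
    step <- abs(nxt - pts)
    diag_step <- step[, 1] == 1 & step[, 2] == 1
    axial_step <- xor(step[, 1] == 1, step[, 2] == 1) & (step[, 1] + step[, 2] == 1)
    total <- total + 0.948 * sum(axial_step) + 1.340 * sum(diag_step)
  }
  total
}

## Euclidean distance from each query point (n x 2, pixel coords, possibly
## fractional) to the nearest point in a reference coordinate set (m x 2).
nearest_dist <- function(query, ref) {
  stopifnot(ncol(query) == 2L, ncol(ref) == 2L, nrow(ref) > 0L)
  vapply(seq_len(nrow(query)), function(i) {
    dx <- ref[, 1] - query[i, 1]
    dy <- ref[, 2] - query[i, 2]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
}

## Rasterize a closed polygon (k x 2, 0-based pixel coords) to a logical mask
## using even-odd point-in-polygon on pixel centres.
polygon_mask <- function(vertices, dim) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L)
  nx <- dim[1]; ny <- dim[2]
  ## pixel centres in 0-based coordinates
  px <- rep(seq_len(nx) - 1L, times = ny)
  py <- rep(seq_len(ny) - 1L, each = nx)
  bnd <- vertices
  if (all(bnd[1, ] == bnd[nrow(bnd), ])) bnd <- bnd[-nrow(bnd), , drop = FALSE]
  inside <- mgcv::in.out(rbind(bnd, bnd[1, ]), cbind(px, py))
  matrix(inside, nx, ny)
}

sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(0)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}
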