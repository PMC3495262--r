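# Nuclei detection, wall positions, the 25 x 25 grid and cell densities.

test_that("detection is exact on disjoint-blob phantoms", {
  ph <- cached_phantom(1)
  cents <- detect_nuclei(ph$images$channels$dapi)
  truth <- ph$truth$nuclei_centroids
  expect_equal(nrow(cents), nrow(truth))        # recall and precision 1.0
  # each detected centroid within 1 px of its true centre
  d <- vapply(seq_len(nrow(cents)), function(i) {
    min(sqrt((truth[, 1] - cents[i, 1])^2 + (truth[, 2] - cents[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 1)
  expect_equal(nrow(detect_nuclei(matrix(0, 50, 50))), 0L)
})

test_that("blobs closer than the separation threshold merge to one", {
  ch <- matrix(0, 40, 40)
  ch[10 + (-1:1), 20 + (-1:1)] <- 200
  ch[15 + (-1:1), 20 + (-1:1)] <- 200
  expect_equal(nrow(detect_nuclei(ch, min_separation = 8)), 1L)
  expect_equal(nrow(detect_nuclei(ch, min_separation = 2)), 2L)
})

test_that("wall positions match a brute-force nearest-border oracle", {
  ph <- make_artery_phantom(small_spec(21, eccentricity = 0.2))
  cents <- ph$truth$nuclei_centroids
  pos <- wall_position(cents, ph$masks)
  expect_true(all(pos >= 0 & pos <= 1))
  # brute force: explicit loops over every border pixel
  lb <- which(arterymorph:::mask_border(ph$masks$lumen), arr.ind = TRUE)
  ob <- which(arterymorph:::mask_border(ph$masks$lumen | ph$masks$wall),
              arr.ind = TRUE)
  oracle <- vapply(seq_len(nrow(cents)), function(i) {
    dl <- Inf; da <- Inf
    for (j in seq_len(nrow(lb)))
      dl <- min(dl, sqrt(sum((lb[j, ] - cents[i, ])^2)))
    for (j in seq_len(nrow(ob)))
      da <- min(da, sqrt(sum((ob[j, ] - cents[i, ])^2)))
    dl / (dl + da)
  }, numeric(1))
  expect_identical(pos, oracle)
  # a centroid outside the wall violates the contract
  expect_error(wall_position(matrix(c(2, 2), 1), ph$masks), "contract")
})

test_that("mid-radius points of a concentric annulus sit at position 0.5", {
  spec <- phantom_spec("muscular_two_lamellae", inner_radius_um = 40,
                       layer_thicknesses_um = c(5, 15, 10), seed = 2)
  ph <- make_artery_phantom(spec)
  ctr <- (dim(ph$masks$wall) + 1) / 2
  mid_r <- 40 + 15  # inner radius + half the 30 um wall
  pts <- rbind(ctr + c(mid_r, 0), ctr + c(0, mid_r), ctr - c(mid_r, 0))
  pos <- wall_position(pts, ph$masks)
  expect_true(all(abs(pos - 0.5) < 0.05))
})

test_that("the 25 x 25 grid conserves mass and normalizes to 1", {
  ph <- cached_phantom(1)
  wp <- ph$truth$nuclei_wall_positions
  cp <- circumferential_position(ph$truth$nuclei_centroids, ph$masks$lumen)
  g <- radial_grid(wp, cp)
  expect_equal(sum(g$grid), length(wp))
  expect_equal(max(g$normalized_grid), 1)
  expect_equal(g$transmural_profile, rowSums(g$grid))
  # degenerate: no nuclei
  g0 <- radial_grid(numeric(0), numeric(0))
  expect_equal(sum(g0$grid), 0)
  expect_equal(max(g0$normalized_grid), 0)
  # one nucleus per transmural bin in one circumferential slot
  wp1 <- (seq_len(25) - 0.5) / 25
  g1 <- radial_grid(wp1, rep(0.5, 25))
  expect_true(all(g1$normalized_grid[g1$grid > 0] == 1))
  # per-column normalization mode
  gc <- radial_grid(wp, cp, normalize = "column")
  occupied_cols <- which(colSums(gc$grid) > 0)
  expect_true(all(apply(gc$normalized_grid[, occupied_cols, drop = FALSE],
                        2, max) == 1))
})

test_that("an inner-wall density excess surfaces in the first profile bins", {
  # positions ramped 3x denser in the inner 10% of the wall
  set.seed(5)
  inner <- runif(150, 0, 0.10)
  rest <- runif(350, 0.10, 1)
  g <- radial_grid(c(inner, rest), runif(500))
  expect_lte(which.max(g$transmural_profile), 3)
})

test_that("cell density is a ratio with unit-consistent invariance", {
  expect_equal(cell_density(100, 10000), 0.01)
  expect_error(cell_density(10, 0), "contract")
  ph <- cached_phantom(1)
  cents <- detect_nuclei(ph$images$channels$dapi)
  d1 <- cell_density(nrow(cents), ph$truth$wall_pixels * 1^2)
  # halving the pixel scale quadruples pixel count per um^2 equivalently
  d2 <- cell_density(nrow(cents), (ph$truth$wall_pixels * 4) * 0.5^2)
  expect_equal(d1, d2)
})
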