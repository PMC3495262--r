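# Radii, hydraulic diameter and the two thickness routes.

disc_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xs <- matrix(rep(seq_len(n), times = n), n, n)
  ys <- matrix(rep(seq_len(n), each = n), n, n)
  (xs - c0)^2 + (ys - c0)^2 <= r^2
}

test_that("closed-form radius and hydraulic-diameter identities hold", {
  expect_equal(equivalent_radius_from_area(pi * 100^2), 100)
  expect_equal(equivalent_radius_from_area(0), 0)
  expect_error(equivalent_radius_from_area(-1), "contract")
  expect_equal(radius_from_perimeter(2 * pi * 80), 80)
  expect_equal(radius_from_perimeter(0), 0)
  r <- 37.5
  expect_equal(hydraulic_diameter(pi * r^2, 2 * pi * r), 2 * r)
  expect_equal(hydraulic_diameter(9^2, 4 * 9), 9)  # square of side s
  expect_error(hydraulic_diameter(10, 0), "contract")
})

test_that("rasterized circles recover radius from area and perimeter", {
  for (r in c(25, 50)) {
    m <- disc_mask(r)
    expect_lt(abs(equivalent_radius_from_area(sum(m)) - r), 0.5)
    r_per <- radius_from_perimeter(arterymorph:::chain_perimeter_px(m))
    expect_lt(abs(r_per - r) / r, 0.02)
  }
})

test_that("ring geometry matches analytic annuli and scales linearly", {
  lum <- disc_mask(50, pad = 35)
  outer <- disc_mask(80, pad = 5)
  masks <- layer_masks(lum, outer & !lum)
  g1 <- ring_geometry(masks, 1)
  expect_lt(abs(g1$inner_radius_um - 50), 0.5)
  expect_lt(abs(g1$outer_radius_um - 80), 0.5)
  expect_lt(abs(g1$mean_thickness_ring_um - 30), 1)
  # doubling the pixel scale doubles all reported lengths
  g2 <- ring_geometry(masks, 2)
  expect_equal(g2$inner_radius_um, 2 * g1$inner_radius_um)
  expect_equal(g2$mean_thickness_ring_um, 2 * g1$mean_thickness_ring_um)
  expect_equal(g2$hydraulic_diameter_um, 2 * g1$hydraulic_diameter_um)
  expect_error(ring_geometry(layer_masks(lum, lum & !lum), 1), "degenerate")
})

test_that("eccentric lumen: hydraulic diameter undershoots the area route", {
  spec <- small_spec(2, eccentricity = 0.25)
  ph <- make_artery_phantom(spec)
  g <- ring_geometry(ph$masks, 1)
  # isoperimetric inequality: non-circular section has D_h < 2 r_area
  expect_lt(g$hydraulic_diameter_um, 2 * g$inner_radius_um)
  # ring thickness still recovers the ground-truth mean thickness
  true_t <- ph$truth$outer_radius_um - ph$truth$inner_radius_um
  expect_lt(abs(g$mean_thickness_ring_um - true_t) / true_t, 0.02)
})

test_that("transmural strip thickness equals area over width exactly", {
  solid <- matrix(FALSE, 200, 60); solid[, 11:50] <- TRUE
  expect_equal(transmural_mean_thickness(solid), 40)
  halves <- matrix(FALSE, 200, 80)
  halves[1:100, 1:30] <- TRUE; halves[101:200, 1:50] <- TRUE
  expect_equal(transmural_mean_thickness(halves), 40)
  st <- make_transmural_strip(small_spec(3), undulation_px = 2)
  expect_equal(transmural_mean_thickness(st$masks$wall),
               sum(st$masks$wall) / nrow(st$masks$wall))
})

test_that("layer thicknesses recover the strip ground truth and add up", {
  spec <- phantom_spec("muscular_two_lamellae", inner_radius_um = 50,
                       layer_thicknesses_um = c(5, 30, 15), seed = 8)
  st <- make_transmural_strip(spec, undulation_px = 3)
  lt <- layer_thicknesses(st$masks)
  expect_lt(max(abs(lt[c("intima", "media", "adventitia")] - c(5, 30, 15))),
            1)
  expect_equal(unname(lt[["intima"]] + lt[["media"]] + lt[["adventitia"]]),
               unname(lt[["total"]]))
  # media = whole wall -> intima collapses to zero
  lm <- layer_masks(st$masks$lumen, st$masks$wall, st$masks$wall)
  lt2 <- layer_thicknesses(lm)
  expect_equal(unname(lt2[["intima"]]), 0)
})

test_that("mean thickness is monotone under wall growth", {
  st <- make_transmural_strip(small_spec(6), undulation_px = 2)
  wall <- st$masks$wall
  t0 <- transmural_mean_thickness(wall)
  grown <- wall | arterymorph:::shift_or4(wall)
  expect_gte(transmural_mean_thickness(grown), t0)
})
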