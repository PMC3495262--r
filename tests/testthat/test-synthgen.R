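# Phantom generator: ground-truth exactness, determinism, geometry
# invariants and the dose-response model.

test_that("ground-truth radii follow the layer construction", {
  spec <- phantom_spec("muscular_two_lamellae", inner_radius_um = 50,
                       layer_thicknesses_um = c(5, 30, 15), seed = 3)
  ph <- make_artery_phantom(spec)
  expect_equal(ph$truth$inner_radius_um, 50)
  expect_equal(ph$truth$outer_radius_um, 100)  # 50 + 5 + 30 + 15
  expect_equal(unname(ph$truth$layer_thickness_um), c(5, 30, 15))
})

test_that("painted fractions equal brute-force painted-pixel ratios exactly", {
  ph <- cached_phantom(11)
  for (ch in c("sma", "cd34", "mac387", "collagen")) {
    expect_identical(ph$truth$fractions[[ch]], painted_fraction(ph, ch))
    # one pixel-quantization unit from the requested fraction
    expect_lt(abs(ph$truth$fractions[[ch]] -
                    small_spec()$constituent_fractions[[ch]]),
              1 / ph$truth$wall_pixels + 1e-12)
  }
  # the painted channel itself reproduces the fraction at noise 0
  quiet <- make_artery_phantom(small_spec(11, noise_sd = 0))
  hot <- sum(quiet$images$channels$sma[quiet$masks$wall] > 100)
  expect_equal(hot / quiet$truth$wall_pixels, quiet$truth$fractions[["sma"]])
})

test_that("nuclei count is round(density x wall area) and blobs are valid", {
  ph <- cached_phantom(1)
  expect_equal(ph$truth$nuclei_count,
               round(small_spec()$nuclei_density_cells_per_um2 *
                       ph$truth$wall_area_um2))
  cents <- ph$truth$nuclei_centroids
  # pairwise disjoint blobs: centre separation over twice the blob radius
  d <- as.matrix(dist(cents)); diag(d) <- Inf
  expect_gt(min(d), 4)
  # wholly inside the wall mask
  expect_true(all(ph$masks$wall[cents]))
})

test_that("generator is deterministic: identical spec gives identical bits", {
  a <- make_artery_phantom(small_spec(5))
  b <- make_artery_phantom(small_spec(5))
  expect_identical(a$images$channels, b$images$channels)
  expect_identical(a$truth$nuclei_centroids, b$truth$nuclei_centroids)
  expect_identical(make_negative_control(small_spec(5))$channels,
                   make_negative_control(small_spec(5))$channels)
})

test_that("analytic and rasterized radii agree within 1 px at eccentricity 0", {
  ph <- cached_phantom(1)
  s <- ph$images$pixel_scale_um_per_px
  r_in_px <- equivalent_radius_from_area(ph$truth$lumen_pixels)
  r_out_px <- equivalent_radius_from_area(ph$truth$lumen_pixels +
                                            ph$truth$wall_pixels)
  expect_lt(abs(r_in_px - ph$truth$inner_radius_um / s), 1)
  expect_lt(abs(r_out_px - ph$truth$outer_radius_um / s), 1)
})

test_that("undersized image raises a sizing error", {
  expect_error(make_artery_phantom(small_spec(1), dim = c(40, 40)),
               "sizing error")
})

test_that("negative control has background-only signal channels", {
  spec <- small_spec(9)
  ctrl <- make_negative_control(spec)
  ph <- cached_phantom(9)
  # specific-channel mean matches the background mean, far below sample
  expect_lt(abs(mean(ctrl$channels$sma) - 40), 1)
  expect_gt(mean(ph$images$channels$sma[ph$masks$wall]),
            mean(ctrl$channels$sma) + 20)
  # calibrating a control against itself finds nothing positive
  cal <- calibrate_threshold(ctrl$channels$sma[ph$masks$wall],
                             ctrl$channels$sma[ph$masks$wall])
  expect_identical(cal$threshold, 256L)
  frac <- area_fraction(ctrl$channels$sma, ph$masks$wall, cal$threshold)
  expect_lte(frac$fraction, 0.01)
})

test_that("PSR pair renders birefringence only on recorded collagen pixels", {
  psr <- make_psr_pair(small_spec(4))
  expect_true(all(psr$truth$birefringent %in% psr$truth$painted_collagen))
  # zero-collagen phantom: polarized image stays black
  spec0 <- small_spec(4)
  spec0$constituent_fractions[["collagen"]] <- 0
  psr0 <- make_psr_pair(spec0)
  expect_true(all(psr0$polarized[psr0$masks$wall] < 50))
})

test_that("dose-response model hits its closed-form anchors", {
  rec <- make_dose_response(2, resting_d = 64, max_d = 96,
                            ec50_log10 = -7.5, noise_sd = 0, seed = 2)
  r <- rec[[1]]
  # saturation toward the maximum at the top of the dose range
  far <- make_dose_response(1, 64, 96, ec50_log10 = -9, hill_slope = 2,
                            noise_sd = 0, seed = 1)[[1]]
  expect_lt(abs(tail(far$diameters_um, 1) - 96), 0.1)
  # sigmoid midpoint: half-maximal dilation at the EC50
  at_ec50 <- r$diameters_um[r$doses_log10_M == -7.5]
  expect_equal(percent_max_dilation(at_ec50, 64, 96), 50)
  expect_equal(basal_tone(r$resting_diameter_um, r$max_diameter_um),
               100 * 64 / 96)
  expect_error(make_dose_response(1, 96, 64), "contract violation")
})

test_that("cohorts are reproducible with distinct per-animal seeds", {
  des <- study_design(
    data.frame(condition = c("NT", "HT"), week = 2, n_animals = 3),
    list(NT_2 = small_spec(), HT_2 = small_spec()),
    master_seed = 99)
  a <- make_cohort(des, render = FALSE)
  b <- make_cohort(des, render = FALSE)
  expect_equal(nrow(a$cohort), 6L)
  expect_false(anyDuplicated(a$cohort$seed) > 0)
  expect_identical(a$cohort, b$cohort)
  expect_error(study_design(
    data.frame(condition = c("NT", "NT"), week = c(2, 2), n_animals = 2),
    list(NT_2 = small_spec())), "duplicate")
})
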