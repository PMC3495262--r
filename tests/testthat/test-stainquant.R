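# Threshold calibration against negative controls and the area-fraction
# quantifiers.

test_that("calibration finds separated signal and flags identical inputs", {
  set.seed(7)
  control <- runif(5000, 0, 50)
  sample_v <- c(runif(5000, 0, 50), rep(200, 400))
  cal <- calibrate_threshold(sample_v, control)
  expect_identical(cal$threshold, 200L)
  same <- calibrate_threshold(control, control)
  expect_identical(same$threshold, 256L)
  expect_true(same$flagged)
})

test_that("calibration is translation-sound", {
  set.seed(8)
  control <- rnorm(4000, 40, 10)
  sample_v <- c(rnorm(3000, 40, 10), rnorm(1000, 180, 10))
  t0 <- calibrate_threshold(sample_v, control)$threshold
  t30 <- calibrate_threshold(sample_v + 30, control + 30)$threshold
  expect_equal(t30, t0 + 30L)
})

test_that("area fraction obeys its boundary and monotone contracts", {
  ph <- cached_phantom(1)
  ch <- ph$images$channels$sma; wall <- ph$masks$wall
  expect_equal(area_fraction(ch, wall, 0)$fraction, 1)
  expect_equal(area_fraction(ch, wall, 256)$fraction, 0)
  fr <- vapply(c(0, 60, 110, 160, 220, 256),
               function(t) area_fraction(ch, wall, t)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
  rec <- area_fraction(ch, wall, 110)
  expect_equal(rec$fraction, rec$positive_pixels / rec$wall_pixels)
  expect_error(area_fraction(ch, wall & FALSE, 110), "degenerate")
})

test_that("negative-control calibration recovers painted fractions", {
  errs <- vapply(1:5, function(s) {
    spec <- small_spec(s + 100)
    ph <- make_artery_phantom(spec)
    ctrl <- make_negative_control(spec)
    cal <- calibrate_threshold(ph$images$channels$sma[ph$masks$wall],
                               ctrl$channels$sma[ph$masks$wall])
    rec <- area_fraction(ph$images$channels$sma, ph$masks$wall,
                         cal$threshold)
    abs(rec$fraction - ph$truth$fractions[["sma"]])
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("VVG elastin survives nuclei-blob removal", {
  ph <- cached_phantom(1)
  vvg <- ph$images$channels$vvg; wall <- ph$masks$wall
  with_rm <- elastin_fraction_vvg(vvg, wall, min_blob_size = 50)
  no_rm <- elastin_fraction_vvg(vvg, wall, min_blob_size = 0)
  expect_gte(no_rm$fraction, with_rm$fraction)   # removal is monotone
  expect_lt(abs(with_rm$fraction - ph$truth$fractions[["elastin"]]), 0.02)
  expect_equal(with_rm$removed_blobs, ph$truth$nuclei_count)
  # an image of only nucleus-sized blobs quantifies to zero elastin
  blobs <- matrix(255, 80, 80)
  for (cc in list(c(20, 20), c(40, 40), c(60, 60)))
    blobs[cc[1] + (-1:1), cc[2] + (-1:1)] <- 30
  allwall <- matrix(TRUE, 80, 80)
  expect_equal(elastin_fraction_vvg(blobs, allwall,
                                    min_blob_size = 50)$fraction, 0)
})

test_that("PSR collagen uses the red ROI and birefringence threshold", {
  psr <- make_psr_pair(small_spec(12))
  rec <- collagen_fraction_psr(psr$brightfield, psr$polarized,
                               psr$masks$wall)
  truth <- psr$truth$birefringent_fraction_of_wall
  expect_lt(abs(rec$fraction - truth), 0.02)
  expect_lte(rec$positive_pixels, rec$roi_pixels)  # positive set in ROI
  # all-black polarized image -> zero collagen
  black <- matrix(0, nrow(psr$polarized), ncol(psr$polarized))
  expect_equal(collagen_fraction_psr(psr$brightfield, black,
                                     psr$masks$wall)$fraction, 0)
  expect_error(collagen_fraction_psr(psr$brightfield, black[1:10, 1:10],
                                     psr$masks$wall), "registration")
})

test_that("batch quantification is total, keyed and order-independent", {
  phs <- lapply(1:3, cached_phantom)
  sets <- setNames(lapply(phs, `[[`, "images"), paste0("img", 1:3))
  walls <- setNames(lapply(phs, function(p) p$masks$wall),
                    paste0("img", 1:3))
  cals <- list(
    synthetic_sma = calibrate_threshold(
      phs[[1]]$images$channels$sma[walls[[1]]],
      make_negative_control(small_spec(1))$channels$sma[walls[[1]]]),
    synthetic_cd34 = calibrate_threshold(
      phs[[1]]$images$channels$cd34[walls[[1]]],
      make_negative_control(small_spec(1))$channels$cd34[walls[[1]]])
  )
  out <- batch_quantify(sets, walls, cals, stains = c("sma", "cd34"))
  expect_equal(nrow(out), 6L)
  out_perm <- batch_quantify(rev(sets), rev(walls), cals,
                             stains = c("sma", "cd34"))
  expect_identical(out, out_perm)
  expect_error(batch_quantify(sets, walls, cals["synthetic_sma"],
                              stains = c("sma", "cd34")), "lookup error")
})
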