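# Two-way ANOVA, Bonferroni adjustment, star coding and report assembly.

test_that("balanced two-way ANOVA matches the hand-computed decomposition", {
  d <- balanced_2x2()
  gc <- two_way_anova(d, "y", "condition", "week")
  # closed-form sums of squares for the balanced 2 x 2 design
  gm <- mean(d$y)
  ss_a <- sum(tapply(d$y, d$condition, function(v) length(v) *
                       (mean(v) - gm)^2))
  ss_b <- sum(tapply(d$y, d$week, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(d$y, list(d$condition, d$week), mean)
  am <- tapply(d$y, d$condition, mean); bm <- tapply(d$y, d$week, mean)
  ss_ab <- 3 * sum((cellm - outer(am, rep(1, 2)) -
                      outer(rep(1, 2), bm) + gm)^2)
  ss_err <- sum((d$y - cellm[cbind(d$condition,
                                   as.character(d$week))])^2)
  tab <- gc$anova
  expect_lt(abs(tab$sumsq[tab$term == "condition"] - ss_a), 1e-10)
  expect_lt(abs(tab$sumsq[tab$term == "week"] - ss_b), 1e-10)
  expect_lt(abs(tab$sumsq[tab$term == "condition:week"] - ss_ab), 1e-10)
  expect_lt(abs(tab$sumsq[tab$term == "Residuals"] - ss_err), 1e-10)
  ms_err <- ss_err / 8
  expect_lt(abs(tab$statistic[tab$term == "condition"] - ss_a / ms_err),
            1e-10)
  # additivity: SS_A + SS_B + SS_AB + SS_error = SS_total
  expect_lt(abs(sum(tab$sumsq) - sum((d$y - gm)^2)) / sum((d$y - gm)^2),
            1e-9)
})

test_that("a constant response yields F = 0 and p = 1 for every effect", {
  d <- balanced_2x2(); d$y <- 5
  gc <- two_way_anova(d, "y", "condition", "week")
  eff <- gc$anova[gc$anova$term != "Residuals", ]
  expect_true(all(eff$statistic == 0))
  expect_true(all(eff$p_value == 1))
})

test_that("unbalanced designs and repeated measures are supported", {
  d <- balanced_2x2()[-1, ]
  gc <- two_way_anova(d, "y", "condition", "week")
  expect_true(all(c("condition", "week", "condition:week") %in%
                    gc$anova$term))
  expect_true(all(gc$anova$p_value >= 0 & gc$anova$p_value <= 1,
                  na.rm = TRUE))
  # repeated measures: vessels tracked across doses
  rec <- c(make_dose_response(4, 64, 96, noise_sd = 2, seed = 1,
                              condition = "NT"),
           make_dose_response(4, 62, 96, noise_sd = 2, seed = 2,
                              condition = "HT", efficacy = 0.5))
  long <- dplyr::bind_rows(lapply(rec, function(r) tibble::tibble(
    vessel = r$vessel_id, condition = r$condition,
    dose = r$doses_log10_M,
    pct = percent_max_dilation(r$diameters_um, r$resting_diameter_um,
                               r$max_diameter_um))))
  gr <- two_way_anova(long, "pct", "condition", "dose", repeated = TRUE,
                      subject = "vessel")
  p_cond <- gr$anova$p_value[gr$anova$term == "condition"]
  expect_lt(p_cond[!is.na(p_cond)][1], 0.05)
  expect_error(two_way_anova(data.frame(y = 1:4, a = "x", b = c(1, 1, 2, 2)),
                             "y", "a", "b"), "design error")
})

test_that("Bonferroni adjustment is capped and monotone", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  p <- runif(50)
  expect_true(all(bonferroni_adjust(p, 7) >= p))
})

test_that("star codes follow the printed thresholds with open intervals", {
  expect_equal(star_code(0.0005), "***")
  expect_equal(star_code(0.03), "*")
  expect_equal(star_code(0.05), "")      # boundary maps to weaker code
  expect_equal(star_code(0.01), "*")
  expect_equal(star_code(0.001), "**")
  expect_error(star_code(1.5), "contract")
  # step function over a p grid
  grid <- seq(0, 1, by = 1e-3)
  codes <- star_code(grid)
  expect_true(all(codes[grid < 0.001] == "***"))
  expect_true(all(codes[grid >= 0.001 & grid < 0.01] == "**"))
  expect_true(all(codes[grid >= 0.01 & grid < 0.05] == "*"))
  expect_true(all(codes[grid >= 0.05] == ""))
})

test_that("report assembly joins tables deterministically", {
  set.seed(2)
  key <- expand.grid(condition = c("NT", "HT"), week = c(2, 8),
                     animal = 1:3, stringsAsFactors = FALSE)
  geom <- cbind(key, wall_thickness_um = rnorm(12, 50, 2) +
                  10 * (key$condition == "HT"))
  frac <- cbind(key, sma_fraction = rnorm(12, 0.3, 0.02))
  nuc <- cbind(key, nuclei_density_per_um2 = rnorm(12, 0.004, 2e-4))
  rep1 <- build_report(geom, frac, nuc)
  expect_equal(nrow(rep1$long), 36L)  # every animal once per measure
  expect_true(all(table(rep1$long$measure) == 12L))
  # order-independence
  rep2 <- build_report(geom[sample(12), ], frac[sample(12), ],
                       nuc[sample(12), ])
  expect_identical(rep1$long, rep2$long)
  expect_identical(rep1$summary, rep2$summary)
  # missing fraction table is flagged, not fatal
  rep3 <- build_report(geom, NULL, nuc)
  expect_true(any(grepl("stain fraction", rep3$flags)))
  expect_false("sma_fraction" %in% rep3$long$measure)
  # a designated condition can be excluded from reporting
  rep4 <- build_report(geom, frac, nuc, drop_condition = "NT")
  expect_false("NT" %in% rep4$long$condition)
  expect_error(build_report(data.frame(x = 1)), "join error")
})
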