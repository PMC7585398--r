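# Rule-based grading: defect detection and classification, segmentation
# grading, alignment, scaling estimation, clipping, factor ranking.

bands_model <- normative_model(between_eye_sd = 2)
test_bands <- normative_bands(bands_model, n_eyes = 500, seed = 5)

test_that("an injected local lesion is recovered as one local region", {
  rec <- simulate_pair(quiet_model(),
                       list(lesion_spec("local", 90, 30, 20, "boxcar")),
                       seed = 9)
  d <- detect_defects(rec$pair, test_bands)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$width_deg - 30), 5)
  expect_identical(d$classification, "local")
})

test_that("widespread below-band thinning is classified widespread", {
  rec <- simulate_pair(quiet_model(),
                       list(lesion_spec("widespread", 180, 270, 8, "boxcar")),
                       seed = 10)
  d <- detect_defects(rec$pair, test_bands)
  expect_equal(nrow(d), 1)
  expect_identical(d$classification, "widespread")
  expect_gte(d$width_deg, 90)
})

test_that("identical visits yield no defect regions", {
  p <- simulate_pair(quiet_model(), seed = 11)$pair$baseline
  pair <- visit_pair("e", p, p)
  expect_equal(nrow(detect_defects(pair, test_bands)), 0)
})

test_that("defect width classification follows the 45/90 degree rules", {
  expect_identical(cprnfl:::classify_run_width(30, 30), "local")
  expect_identical(cprnfl:::classify_run_width(44.9, 44.9), "local")
  expect_identical(cprnfl:::classify_run_width(60, 95), "widespread")
  expect_identical(cprnfl:::classify_run_width(120, 120), "widespread")
  expect_identical(cprnfl:::classify_run_width(60, 60), "intermediate")
})

test_that("boxcar lesion widths 10-40 deg are recovered within 2 grid steps", {
  m <- normative_model(between_eye_sd = 2, within_eye_profile_sd = 0.5,
                       g_retest_sd = 0.6)
  bands <- normative_bands(m, n_eyes = 500, seed = 6)
  set.seed(23)
  widths <- runif(300, 10, 40)
  centers <- runif(300, 0, 360)
  seeds <- sample.int(1e6, 300)
  step <- 360 / 768
  for (i in seq_along(widths)) {
    rec <- simulate_pair(m, list(lesion_spec("local", centers[i], widths[i],
                                             20, "boxcar")), seed = seeds[i])
    d <- detect_defects(rec$pair, bands)
    expect_equal(nrow(d), 1)
    expect_lt(abs(d$width_deg - widths[i]), 2 * step + step)  # grid realization
    expect_false(d$classification == "widespread")
  }
})

test_that("segmentation grading recovers injected regions above the 5 deg rule", {
  m0 <- quiet_model()
  art <- artifact_spec("segmentation", "followup", region = c(100, 136),
                       magnitude = -20)
  rec <- simulate_pair(m0, artifacts = list(art), seed = 10)
  g <- grade_segmentation(rec, tol = 5)
  expect_equal(nrow(g), 1)
  expect_identical(g$visit, "followup")
  expect_lt(abs(g$width_deg - 36), 1.5)
  expect_equal(g$mean_error_um, -20, tolerance = 0.01)
  # a 4-degree region stays below the grading rule
  small <- artifact_spec("schisis", "followup", region = c(100, 104),
                         magnitude = -20)
  rec2 <- simulate_pair(m0, artifacts = list(small), seed = 10)
  expect_equal(nrow(grade_segmentation(rec2, tol = 5)), 0)
  rec$latent_baseline <- NULL
  expect_error(grade_segmentation(rec), class = "cprnfl_unsupported_error")
})

test_that("artifact-free eyes rarely trigger segmentation grading", {
  m <- normative_model()
  set.seed(29)
  seeds <- sample.int(1e6, 200)
  hits <- vapply(seeds, function(s) {
    nrow(grade_segmentation(simulate_pair(m, seed = s),
                            tol = 5 * m$within_eye_profile_sd)) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.01)
})

test_that("alignment check compares vessel shifts against shadow widths", {
  base <- marked_profile(c(70, 110, 250, 290), shadow_width = 3)
  same <- visit_pair("e", base, base)
  a0 <- check_alignment(same)
  expect_false(a0$misaligned)
  expect_equal(a0$shift_deg, 0)
  shifted5 <- marked_profile(c(70, 110, 250, 290) + 5, shadow_width = 3)
  a5 <- check_alignment(visit_pair("e", base, shifted5))
  expect_true(a5$misaligned)
  expect_equal(a5$shift_deg, 5)
  shifted2 <- marked_profile(c(70, 110, 250, 290) + 2, shadow_width = 3)
  a2 <- check_alignment(visit_pair("e", base, shifted2))
  expect_false(a2$misaligned)
  expect_equal(a2$shift_deg, 2)
  bare <- constant_profile(80)
  expect_error(check_alignment(visit_pair("e", bare, bare)),
               class = "cprnfl_unsupported_error")
})

test_that("scaling estimate is exact on proportional pairs and robust to noise", {
  p <- simulate_pair(quiet_model(), seed = 12)$pair$baseline
  q <- p
  q$thickness <- 1.03 * p$thickness
  est <- estimate_scaling(visit_pair("e", p, q))
  expect_equal(est$s, 0.03, tolerance = 1e-12)
  expect_true(est$flagged)
  est0 <- estimate_scaling(visit_pair("e", p, p))
  expect_equal(est0$s, 0)
  expect_false(est0$flagged)
  set.seed(30)
  q2 <- p
  q2$thickness <- 0.95 * p$thickness + rnorm(768, 0, 1)
  est2 <- estimate_scaling(visit_pair("e", p, q2))
  expect_lt(abs(est2$s - (-0.05)), 0.005)
  # insufficient valid overlap
  q3 <- p
  q3$valid[1:500] <- FALSE
  expect_error(estimate_scaling(visit_pair("e", p, q3)),
               class = "cprnfl_unsupported_error")
})

test_that("clipping detection finds collapsed or masked runs", {
  p <- constant_profile(80)
  p$valid[p$angles >= 30 & p$angles <= 90] <- FALSE
  d <- detect_clipping(p)
  expect_equal(nrow(d), 1)
  expect_equal(d$start_deg, 30, tolerance = 0.5)
  expect_equal(d$width_deg, 60, tolerance = 1)
  expect_equal(nrow(detect_clipping(constant_profile(80))), 0)
})

test_that("a 60 deg follow-up clip on an 80 um eye drives delta-G near -11.7", {
  rec <- simulate_pair(flat_model(80),
                       artifacts = list(artifact_spec("clipping", "followup",
                                                      region = c(30, 90),
                                                      floor_um = 10)),
                       seed = 13)
  d <- detect_clipping(rec$pair$followup)
  expect_equal(d$width_deg, 60, tolerance = 1)
  expect_equal(rec$pair$delta_g, -(60 / 360) * 70, tolerance = 0.01)
})

test_that("factor ranking orders causes by absolute delta-G contribution", {
  m0 <- flat_model(80)
  rec <- simulate_pair(
    m0, list(lesion_spec("local", 90, 30, 12, "boxcar")),
    list(artifact_spec("segmentation", "followup", region = c(200, 239),
                       magnitude = -24)),
    seed = 14)
  rk <- attribute_factors(rec)$factor_ranking
  expect_identical(rk$cause, c("segmentation", "local"))
  expect_identical(rk$rank, 1:2)
  rec2 <- simulate_pair(m0, artifacts = list(artifact_spec("scaling", "followup",
                                                           magnitude = -0.04)),
                        seed = 15)
  rk2 <- attribute_factors(rec2)$factor_ranking
  expect_identical(rk2$cause, "scaling")
  rec3 <- simulate_pair(m0, list(lesion_spec("local", 90, 30, 12, "boxcar")),
                        seed = 16)
  rk3 <- attribute_factors(rec3)$factor_ranking
  expect_identical(rk3$cause, "local")
})
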