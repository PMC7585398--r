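# Synthetic cohort generator: profile construction, lesion and artifact
# injection, paired-visit simulation, and noise calibration.

test_that("degenerate model with no peaks and no noise gives a constant profile", {
  p <- make_normative_profile(flat_model(80), seed = 1)
  expect_equal(p$thickness, rep(80, 768))
  expect_equal(nrow(p$vessels), 0)
})

test_that("default profile mean matches the analytic mean shape integral", {
  m <- quiet_model()
  g_analytic <- analytic_mean_g(m)
  expect_gt(g_analytic, 70)
  expect_lt(g_analytic, 120)
  p <- make_normative_profile(m, seed = 3)
  expect_equal(global_mean(p), g_analytic, tolerance = 1e-4)
  # vessel markers populated at the model's vessel centers
  expect_equal(p$vessels$center_deg, m$vessels$center_deg)
})

test_that("between-eye spread of profile means follows the configured SDs", {
  m <- normative_model()
  set.seed(42)
  seeds <- sample.int(1e6, 800)
  g <- vapply(seeds, function(s) global_mean(make_normative_profile(m, s)), 0)
  diffs <- g[seq(1, 799, 2)] - g[seq(2, 800, 2)]
  sd_diff <- sqrt(2 * (m$between_eye_sd^2 + (m$g_retest_sd / sqrt(2))^2))
  expect_gte(mean(abs(diffs) < 3 * sd_diff), 0.99)
})

test_that("boxcar lesions reduce the global mean by exactly width*depth/360", {
  cp <- constant_profile(80)
  l1 <- apply_lesion(cp, lesion_spec("local", 180, 30, 12, "boxcar"))
  expect_equal(global_mean(l1), 79, tolerance = 1e-12)
  l2 <- apply_lesion(cp, lesion_spec("widespread", 180, 90, 4, "boxcar"))
  expect_equal(global_mean(l2), 79, tolerance = 1e-12)
  # thinning confined to the lesion support; clamped at zero
  deep <- apply_lesion(constant_profile(10),
                       lesion_spec("local", 180, 30, 40, "boxcar"))
  expect_true(all(deep$thickness >= 0))
  expect_equal(sum(deep$thickness == 0), 64)   # 30 deg at 768 samples
})

test_that("raised-cosine lesion mean drop matches an independent quadrature", {
  cp <- constant_profile(120)
  les <- lesion_spec("local", 77.3, 33, 9.5, "raised_cosine")
  got <- global_mean(cp) - global_mean(apply_lesion(cp, les))
  d <- pmin(abs(cp$angles - les$center_deg) %% 360,
            360 - abs(cp$angles - les$center_deg) %% 360)
  oracle <- sum(ifelse(d < les$width_deg / 2,
                       les$depth_um * (1 + cos(2 * pi * d / les$width_deg)), 0)) /
    length(cp$angles)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("lesion spec enforces the 45/90 degree width rules", {
  expect_error(lesion_spec("local", 90, 50, 5), class = "cprnfl_parameter_error")
  expect_error(lesion_spec("widespread", 90, 60, 5), class = "cprnfl_parameter_error")
  expect_error(lesion_spec("local", 90, 30, 0), class = "cprnfl_parameter_error")
})

test_that("scaling, segmentation and rotation artifacts act as specified", {
  cp <- constant_profile(80)
  # 5% shrink of an 80 um profile removes exactly 4 um
  sc <- apply_artifact(cp, artifact_spec("scaling", "followup", magnitude = -0.05))
  expect_equal(sc$thickness, rep(76, 768))
  expect_error(artifact_spec("scaling", "followup", magnitude = -0.06),
               class = "cprnfl_parameter_error")
  # segmentation offset -20 um over 36 deg on an 80 um profile: G = 78
  cp720 <- constant_profile(80, n = 720L)
  seg <- apply_artifact(cp720, artifact_spec("segmentation", "followup",
                                             region = c(60, 96), magnitude = -20))
  expect_equal(global_mean(seg), 78, tolerance = 1e-12)
  # rotation by any whole-grid-step angle leaves the mean unchanged
  p <- make_normative_profile(normative_model(), seed = 8)
  for (deg in c(0.46875, 5.15625, 90, 247.5)) {
    r <- apply_artifact(p, artifact_spec("rotation", "followup", magnitude = deg))
    expect_equal(global_mean(r), global_mean(p), tolerance = 1e-13)
    expect_setequal(round(r$thickness, 9), round(p$thickness, 9))
  }
})

test_that("clipping collapses the region and invalidates its mask", {
  cp <- constant_profile(80)
  cl <- apply_artifact(cp, artifact_spec("clipping", "followup",
                                         region = c(30, 90), floor_um = 10))
  sel <- cp$angles >= 30 & cp$angles < 90
  expect_true(all(!cl$valid[sel]))
  expect_true(all(cl$thickness[sel] == 10))
  expect_true(all(cl$valid[!sel]))
  # clipping wins over segmentation on the same samples
  both <- cprnfl:::apply_visit_effects(cp, list(
    artifact_spec("segmentation", "followup", region = c(30, 90), magnitude = 15),
    artifact_spec("clipping", "followup", region = c(30, 90))),
    noise = numeric(768))$profile
  expect_true(all(both$thickness[sel] == 10))
})

test_that("zero-noise pairs obey exact lesion linearity", {
  m <- flat_model(80)
  rec0 <- simulate_pair(m, seed = 5)
  expect_identical(rec0$pair$delta_g, 0)
  expect_identical(rec0$truth_label, "NP")
  rec <- simulate_pair(m, list(lesion_spec("local", 90, 30, 12, "boxcar")), seed = 5)
  expect_equal(rec$pair$delta_g, -1, tolerance = 1e-12)
  expect_identical(rec$truth_label, "P")
})

test_that("simulate_pair is deterministic given the seed", {
  m <- normative_model()
  a <- simulate_pair(m, seed = 99)
  b <- simulate_pair(m, seed = 99)
  expect_identical(a$pair$baseline$thickness, b$pair$baseline$thickness)
  expect_identical(a$pair$followup$thickness, b$pair$followup$thickness)
})

test_that("delta-G test-retest noise matches the calibrated SD", {
  m <- normative_model()
  rt <- simulate_testretest(m, 2000, seed = 7)
  dg <- vapply(rt, `[[`, 0, "delta_g")
  expect_equal(sd(dg), m$g_retest_sd, tolerance = 0.05)
  # fraction below the rule-of-5 threshold matches the normal tail
  expect_lt(abs(mean(dg <= -5) - pnorm(-5 / m$g_retest_sd)), 0.012)
})

test_that("no-change 95% limits of |delta-G| sit just below 5 um", {
  rt <- simulate_testretest(normative_model(), 2000, seed = 17)
  lim <- quantile(abs(vapply(rt, `[[`, 0, "delta_g")), 0.95, names = FALSE)
  expect_gte(lim, 4.2)
  expect_lte(lim, 5.0)
})

test_that("test-retest baselines cover the requested G range", {
  rt <- simulate_testretest(normative_model(), 400, seed = 19, g_range = c(60, 110))
  gb <- vapply(rt, `[[`, 0, "g_baseline")
  expect_gte(diff(range(gb)) / 50, 0.8)
  expect_error(simulate_testretest(normative_model(), 1),
               class = "cprnfl_parameter_error")
})

test_that("zero-noise widespread-only cohort has exact delta-G by label", {
  cfg <- cohort_config(n_P = 30, n_NP = 61, model = flat_model(80),
                       p_local = 0,
                       widespread_width = c(270, 270),
                       widespread_depth = c(6, 6),
                       lesion_shape = "boxcar",
                       seg_prevalence = 0, clip_prevalence = 0,
                       scaling_prevalence = 0, rotation_prevalence = 0)
  coh <- simulate_cohort(cfg, seed = 2)
  dg <- vapply(coh, function(e) e$pair$delta_g, 0)
  lab <- vapply(coh, `[[`, "", "truth_label")
  expect_equal(unname(dg[lab == "P"]), rep(-4.5, 30), tolerance = 1e-12)
  expect_equal(unname(dg[lab == "NP"]), rep(0, 61), tolerance = 1e-12)
})

test_that("injected segmentation prevalence is binomial around the config rate", {
  cfg <- cohort_config(n_P = 0, n_NP = 200, seg_prevalence = 0.44,
                       clip_prevalence = 0, scaling_prevalence = 0,
                       rotation_prevalence = 0)
  coh <- simulate_cohort(cfg, seed = 31)
  count <- attr(coh, "injection_summary")
  count <- count$count[count$factor == "segmentation"]
  expect_lt(abs(count - 0.44 * 200), 4 * sqrt(200 * 0.44 * 0.56))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- cohort_config(n_P = 4, n_NP = 6)
  a <- simulate_cohort(cfg, seed = 77)
  b <- simulate_cohort(cfg, seed = 77)
  expect_identical(lapply(a, function(e) e$pair$followup$thickness),
                   lapply(b, function(e) e$pair$followup$thickness))
  expect_error(cohort_config(n_P = -1), class = "cprnfl_parameter_error")
})
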