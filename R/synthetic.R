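# Synthetic paired-visit cpRNFL cohort generator.
#
# Profiles are built as: double-hump normative mean shape (superior and
# inferior raised-cosine peaks over a temporal floor) + vessel bumps
# + an eye-level offset (between-eye variation) + smoothed test-retest
# noise.  Progression lesions and measurement artifacts (segmentation
# offsets, clipping, global scaling, rotation) are injected with full
# ground truth so every downstream stage can be verified.

#' Normative profile model
#'
#' Defines the healthy mean shape and the noise structure.  The test-retest
#' calibration constant is `g_retest_sd`: the SD of delta-G under no change.
#' The default 2.4 um puts the 95% limits of |delta-G| at 1.96 * 2.4 ~ 4.7
#' um, just below the informal 5 um clinical limit.  Per-visit G noise is
#' `g_retest_sd / sqrt(2)` so that the difference of two visits has SD
#' `g_retest_sd` exactly.
#'
#' @param base_level Temporal floor of the profile, um.
#' @param peaks `data.frame(center_deg, amplitude_um, width_deg)` for the
#'   superior and inferior humps; `width_deg` is the raised-cosine
#'   half-support (also its FWHM), so each peak adds
#'   `amplitude * width / 360` um to the global mean.
#' @param vessels `data.frame(center_deg, amplitude_um, width_deg,
#'   shadow_width_deg)` for vessel bumps and their shadow landmarks.
#' @param between_eye_sd SD of the eye-level thickness offset, um.
#' @param within_eye_profile_sd Pointwise test-retest noise SD, um (the
#'   textured, zero-mean part; smoothed over ~5 degrees).
#' @param g_retest_sd SD of delta-G under no change, um (contractual).
#' @param noise_smooth_deg Smoothing window for the textured noise, degrees.
#' @return A `normative_model` object.
#' @export
normative_model <- function(base_level = 70,
                            peaks = data.frame(
                              center_deg = c(90, 270),
                              amplitude_um = c(60, 65),
                              width_deg = c(70, 70)),
                            vessels = data.frame(
                              center_deg = c(70, 110, 250, 290),
                              amplitude_um = 15,
                              width_deg = 6,
                              shadow_width_deg = 3),
                            between_eye_sd = 8,
                            within_eye_profile_sd = 2,
                            g_retest_sd = 2.4,
                            noise_smooth_deg = 5) {
  if (any(c(between_eye_sd, within_eye_profile_sd, g_retest_sd) < 0))
    abort_param("noise SDs must be >= 0")
  if (any(peaks$width_deg <= 0) || (nrow(vessels) && any(vessels$width_deg <= 0)))
    abort_param("peak and vessel widths must be > 0")
  if (any(peaks$center_deg < 0 | peaks$center_deg >= 360) ||
      (nrow(vessels) && any(vessels$center_deg < 0 | vessels$center_deg >= 360)))
    abort_param("centers must lie in [0, 360)")
  m <- structure(
    list(base_level = base_level, peaks = peaks, vessels = vessels,
         between_eye_sd = between_eye_sd,
         within_eye_profile_sd = within_eye_profile_sd,
         g_retest_sd = g_retest_sd, noise_smooth_deg = noise_smooth_deg),
    class = "normative_model")
  if (min(mean_shape(m)) <= 0)
    abort_param("mean profile must be > 0 everywhere")
  m
}

# Raised-cosine bump: amplitude * 0.5 * (1 + cos(pi * d / w)) for circular
# distance d < w (w = half-support).  Integral over the circle = A * w.
rc_bump <- function(angles, center, amplitude, width) {
  d <- circ_dist(angles, center)
  ifelse(d < width, amplitude * 0.5 * (1 + cos(pi * d / width)), 0)
}

#' Noise-free mean profile of a normative model
#' @param model A [normative_model()].
#' @param n Grid size.
#' @return Numeric thickness vector, um.
#' @export
mean_shape <- function(model, n = 768L) {
  angles <- profile_grid(n)
  y <- rep(model$base_level, n)
  for (i in seq_len(nrow(model$peaks)))
    y <- y + rc_bump(angles, model$peaks$center_deg[i],
                     model$peaks$amplitude_um[i], model$peaks$width_deg[i])
  for (i in seq_len(nrow(model$vessels)))
    y <- y + rc_bump(angles, model$vessels$center_deg[i],
                     model$vessels$amplitude_um[i], model$vessels$width_deg[i])
  y
}

#' Analytic global mean of the model's mean shape
#' @param model A [normative_model()].
#' @return Micrometers: `base + sum(A_i * w_i) / 360` over peaks and vessels.
#' @export
analytic_mean_g <- function(model) {
  model$base_level +
    (sum(model$peaks$amplitude_um * model$peaks$width_deg) +
       sum(model$vessels$amplitude_um * model$vessels$width_deg)) / 360
}

# One visit's noise realization: smoothed zero-mean texture plus a global
# offset with SD g_retest_sd / sqrt(2), so mean(noise) is exactly the
# per-visit G-level noise.  Draw order is fixed for determinism.
visit_noise <- function(model, n) {
  noise <- numeric(n)
  if (model$within_eye_profile_sd > 0) {
    e <- stats::rnorm(n)
    k <- max(1L, round(model$noise_smooth_deg / (360 / n)))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) {
      ext <- c(e[(n - (k %/% 2) + 1L):n], e, e[1:(k %/% 2)])
      e <- as.numeric(stats::filter(ext, rep(1 / k, k), sides = 2))[(k %/% 2 + 1L):(k %/% 2 + n)]
      e <- e * sqrt(k)                     # restore unit pointwise SD
    }
    noise <- (e - mean(e)) * model$within_eye_profile_sd
  }
  if (model$g_retest_sd > 0)
    noise <- noise + stats::rnorm(1, 0, model$g_retest_sd / sqrt(2))
  noise
}

vessel_markers <- function(model) {
  if (!nrow(model$vessels)) return(empty_vessels())
  data.frame(center_deg = model$vessels$center_deg,
             shadow_width_deg = model$vessels$shadow_width_deg)
}

#' Draw one healthy profile from a normative model
#'
#' @param model A [normative_model()].
#' @param seed Integer seed (one profile per seed; deterministic).
#' @param n Grid size.
#' @return A [thickness_profile()] with vessel markers populated.
#' @export
make_normative_profile <- function(model, seed, n = 768L) {
  stopifnot(inherits(model, "normative_model"))
  set.seed(seed)
  offset <- if (model$between_eye_sd > 0) stats::rnorm(1, 0, model$between_eye_sd) else 0
  noise <- visit_noise(model, n)
  thickness_profile(pmax(mean_shape(model, n) + offset + noise, 0),
                    vessels = vessel_markers(model))
}

# ---- lesions -------------------------------------------------------------

#' Progression lesion specification
#'
#' @param kind `"local"` (arcuate defect, width < 45 degrees) or
#'   `"widespread"` (thinning over >= 90 degrees).
#' @param center_deg Lesion center, degrees.
#' @param width_deg Angular support width, degrees.
#' @param depth_um Mean thinning over the lesion support, um (> 0).
#' @param shape `"raised_cosine"` (default; peak thinning = 2 * depth) or
#'   `"boxcar"` (uniform thinning = depth; exact arithmetic).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(kind = c("local", "widespread"), center_deg, width_deg,
                        depth_um, shape = c("raised_cosine", "boxcar")) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (depth_um <= 0) abort_param("lesion depth must be > 0")
  if (kind == "local" && width_deg >= 45)
    abort_param("a local lesion must be < 45 degrees wide")
  if (kind == "widespread" && width_deg < 90)
    abort_param("a widespread lesion must be >= 90 degrees wide")
  structure(list(kind = kind, center_deg = center_deg %% 360,
                 width_deg = width_deg, depth_um = depth_um, shape = shape),
            class = "lesion_spec")
}

# Pointwise thinning implied by a lesion, evaluated on a grid.
lesion_depth_at <- function(lesion, angles) {
  if (lesion$shape == "boxcar") {
    sel <- in_arc(angles, lesion$center_deg - lesion$width_deg / 2, lesion$width_deg)
    ifelse(sel, lesion$depth_um, 0)
  } else {
    d <- circ_dist(angles, lesion$center_deg)
    w <- lesion$width_deg
    ifelse(d < w / 2, lesion$depth_um * (1 + cos(2 * pi * d / w)), 0)
  }
}

#' Apply a lesion to a profile
#'
#' Thickness is reduced only on the lesion support and clamped at 0.  For a
#' boxcar lesion realized on the grid, the global-mean drop is exactly
#' `n_lesion_samples * depth / n`.
#'
#' @param profile A [thickness_profile()].
#' @param lesion A [lesion_spec()].
#' @return The modified profile.
#' @export
apply_lesion <- function(profile, lesion) {
  stopifnot(inherits(lesion, "lesion_spec"))
  red <- lesion_depth_at(lesion, profile$angles)
  profile$thickness <- pmax(profile$thickness - red, 0)
  profile
}

# ---- artifacts -----------------------------------------------------------

#' Measurement-artifact specification
#'
#' @param kind One of `"segmentation"`, `"schisis"`, `"clipping"`,
#'   `"scaling"`, `"rotation"`.
#' @param visit `"baseline"` or `"followup"`.
#' @param region `c(start_deg, end_deg)` half-open arc for segmentation,
#'   schisis and clipping; ignored for scaling and rotation (whole scan).
#' @param magnitude Signed um offset (segmentation, schisis), unitless
#'   fraction s with `|s| <= 0.05` (scaling), or degrees (rotation).
#' @param floor_um Collapse value for clipped samples, um (clipping only).
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(kind = c("segmentation", "schisis", "clipping",
                                   "scaling", "rotation"),
                          visit = c("baseline", "followup"),
                          region = NULL, magnitude = 0, floor_um = 10) {
  kind <- match.arg(kind)
  visit <- match.arg(visit)
  if (kind %in% c("segmentation", "schisis", "clipping")) {
    if (is.null(region) || length(region) != 2L)
      abort_param(sprintf("%s artifact needs region = c(start_deg, end_deg)", kind))
    width <- (region[2] - region[1]) %% 360
    if (width == 0) width <- 360
    if (kind == "segmentation" && width <= 5)
      abort_param("a graded segmentation region must span more than 5 degrees")
  }
  if (kind == "scaling" && abs(magnitude) > 0.05)
    abort_param("|scaling fraction| must be <= 0.05")
  structure(list(kind = kind, visit = visit, region = region,
                 magnitude = magnitude, floor_um = floor_um),
            class = "artifact_spec")
}

#' Apply a measurement artifact to a profile
#'
#' Segmentation/schisis add a signed offset over the region; scaling
#' multiplies the whole profile by `1 + s`; rotation circularly shifts
#' thickness, validity and vessel markers by the nearest whole grid step;
#' clipping sets the region's validity mask FALSE and collapses its measured
#' thickness to `floor_um`.
#'
#' @param profile A [thickness_profile()].
#' @param artifact An [artifact_spec()].
#' @return The modified profile.
#' @export
apply_artifact <- function(profile, artifact) {
  stopifnot(inherits(artifact, "artifact_spec"))
  n <- length(profile$angles)
  region_sel <- function() {
    width <- (artifact$region[2] - artifact$region[1]) %% 360
    if (width == 0) width <- 360
    in_arc(profile$angles, artifact$region[1], width)
  }
  switch(artifact$kind,
    segmentation = , schisis = {
      sel <- region_sel()
      profile$thickness[sel] <- pmax(profile$thickness[sel] + artifact$magnitude, 0)
    },
    scaling = {
      profile$thickness <- profile$thickness * (1 + artifact$magnitude)
    },
    rotation = {
      step <- 360 / n
      k <- round(artifact$magnitude / step) %% n
      if (k != 0) {
        idx <- ((seq_len(n) - 1L - k) %% n) + 1L   # new[i] = old[i - k]
        profile$thickness <- profile$thickness[idx]
        profile$valid <- profile$valid[idx]
        profile$vessels$center_deg <- (profile$vessels$center_deg + k * step) %% 360
      }
    },
    clipping = {
      sel <- region_sel()
      profile$valid[sel] <- FALSE
      profile$thickness[sel] <- artifact$floor_um
    })
  profile
}

# Canonical per-visit construction chain shared by simulate_pair() and
# decompose_delta_g(): segmentation/schisis, then scaling, then rotation,
# then noise, then clipping (clipping overrides noise on its region).
apply_visit_effects <- function(latent, artifacts, noise, trace = FALSE) {
  kind_order <- c("segmentation", "schisis", "scaling", "rotation", "clipping")
  artifacts <- artifacts[order(match(vapply(artifacts, `[[`, "", "kind"), kind_order))]
  pre_clip <- Filter(function(a) a$kind != "clipping", artifacts)
  clips <- Filter(function(a) a$kind == "clipping", artifacts)
  tr <- list()
  note <- function(kind, region, before, after) {
    if (!trace) return()
    reg <- if (is.null(region)) c(0, 360) else region
    tr[[length(tr) + 1L]] <<- list(kind = kind, start_deg = reg[1], end_deg = reg[2],
                                   dG = mean(after$thickness) - mean(before$thickness))
  }
  prof <- latent
  for (a in pre_clip) {
    nxt <- apply_artifact(prof, a)
    note(a$kind, a$region, prof, nxt)
    prof <- nxt
  }
  if (any(noise != 0)) {
    nxt <- prof
    nxt$thickness <- pmax(nxt$thickness + noise, 0)
    note("noise", NULL, prof, nxt)
    prof <- nxt
  }
  for (a in clips) {
    nxt <- apply_artifact(prof, a)
    note(a$kind, a$region, prof, nxt)
    prof <- nxt
  }
  list(profile = prof, trace = tr)
}

# ---- paired-visit simulation --------------------------------------------

#' Simulate one eye's baseline/follow-up pair with ground truth
#'
#' Baseline = normative shape + eye offset + baseline artifacts + noise;
#' follow-up = the same latent eye + lesions + follow-up artifacts +
#' independent noise.  The artifact-free noise-free profiles of both visits
#' (latent truth) and the noise realizations are stored so the observed
#' delta-G can be decomposed exactly.
#'
#' @param model A [normative_model()].
#' @param lesions List of [lesion_spec()] (applied at follow-up).
#' @param artifacts List of [artifact_spec()].
#' @param seed Integer seed; the pair is deterministic given the seed.
#' @param eye_id Identifier.
#' @param g_target Optional baseline G target, um (overrides the random
#'   eye-level offset).
#' @param n Grid size.
#' @return An `eye_record`: fields `eye_id`, `truth_label` (`"P"` iff any
#'   lesion), `pair` ([visit_pair()]), `lesions`, `artifacts`,
#'   `latent_baseline`, `latent_followup`, `noise_baseline`,
#'   `noise_followup`.
#' @export
simulate_pair <- function(model, lesions = list(), artifacts = list(),
                          seed = 1L, eye_id = "eye1", g_target = NULL,
                          n = 768L) {
  stopifnot(inherits(model, "normative_model"))
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (inherits(artifacts, "artifact_spec")) artifacts <- list(artifacts)
  set.seed(seed)
  shape <- mean_shape(model, n)
  offset <- if (!is.null(g_target)) g_target - mean(shape)
            else if (model$between_eye_sd > 0) stats::rnorm(1, 0, model$between_eye_sd)
            else 0
  noise_b <- visit_noise(model, n)
  noise_f <- visit_noise(model, n)
  vm <- vessel_markers(model)
  latent_b <- thickness_profile(pmax(shape + offset, 0), vessels = vm,
                                eye_id = eye_id, visit = "baseline")
  latent_f <- latent_b
  latent_f$visit <- "followup"
  for (les in lesions) latent_f <- apply_lesion(latent_f, les)
  arts_b <- Filter(function(a) a$visit == "baseline", artifacts)
  arts_f <- Filter(function(a) a$visit == "followup", artifacts)
  obs_b <- apply_visit_effects(latent_b, arts_b, noise_b)$profile
  obs_f <- apply_visit_effects(latent_f, arts_f, noise_f)$profile
  structure(
    list(eye_id = eye_id,
         truth_label = if (length(lesions)) "P" else "NP",
         pair = visit_pair(eye_id, obs_b, obs_f),
         lesions = lesions, artifacts = artifacts,
         latent_baseline = latent_b, latent_followup = latent_f,
         noise_baseline = noise_b, noise_followup = noise_f),
    class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record> %s [%s]: dG = %+.2f um, %d lesion(s), %d artifact(s)\n",
              x$eye_id, x$truth_label, x$pair$delta_g,
              length(x$lesions), length(x$artifacts)))
  invisible(x)
}

#' Cohort composition and injection configuration
#'
#' Defaults emulate the study conditions: 30 progressing (P) and 61
#' non-progressing (NP) eyes; segmentation-artifact prevalence 0.442 (38 of
#' 86 graded eyes), clipping 0.012 (1 of 86), scaling 0.053 (8 of 150) and
#' rotation 0.067 (10 of 150).
#'
#' @param n_P,n_NP Numbers of progressing and non-progressing eyes.
#' @param model A [normative_model()].
#' @param p_local Probability a P eye's lesion is local (vs widespread).
#' @param local_width,local_depth,widespread_width,widespread_depth Uniform
#'   ranges (degrees, um) for lesion geometry.
#' @param lesion_shape `"raised_cosine"` or `"boxcar"`.
#' @param seg_prevalence,seg_width,seg_magnitude Segmentation artifact
#'   prevalence and uniform ranges (degrees, um; sign random).
#' @param clip_prevalence,clip_width Clipping prevalence and width range.
#' @param scaling_prevalence,scaling_max Scaling prevalence and |s| bound.
#' @param rotation_prevalence,rotation_max Rotation prevalence and maximum
#'   shift (degrees).
#' @param n Grid size.
#' @return A `cohort_config` object (a validated list).
#' @export
cohort_config <- function(n_P = 30L, n_NP = 61L, model = normative_model(),
                          p_local = 0.5,
                          local_width = c(15, 40), local_depth = c(5, 15),
                          widespread_width = c(90, 270), widespread_depth = c(3, 8),
                          lesion_shape = "raised_cosine",
                          seg_prevalence = 0.442, seg_width = c(6, 40),
                          seg_magnitude = c(5, 20),
                          clip_prevalence = 0.012, clip_width = c(20, 60),
                          scaling_prevalence = 0.053, scaling_max = 0.05,
                          rotation_prevalence = 0.067, rotation_max = 6,
                          n = 768L) {
  if (n_P < 0 || n_NP < 0) abort_param("eye counts must be non-negative")
  structure(as.list(environment()), class = "cohort_config")
}

draw_lesion <- function(cfg) {
  if (stats::runif(1) < cfg$p_local) {
    hemi <- if (stats::runif(1) < 0.5) 90 else 270
    lesion_spec("local", center_deg = hemi + stats::runif(1, -40, 40),
                width_deg = stats::runif(1, cfg$local_width[1], cfg$local_width[2]),
                depth_um = stats::runif(1, cfg$local_depth[1], cfg$local_depth[2]),
                shape = cfg$lesion_shape)
  } else {
    lesion_spec("widespread", center_deg = stats::runif(1, 0, 360),
                width_deg = stats::runif(1, cfg$widespread_width[1], cfg$widespread_width[2]),
                depth_um = stats::runif(1, cfg$widespread_depth[1], cfg$widespread_depth[2]),
                shape = cfg$lesion_shape)
  }
}

draw_artifacts <- function(cfg) {
  arts <- list()
  rvisit <- function() sample(c("baseline", "followup"), 1L)
  if (stats::runif(1) < cfg$seg_prevalence) {
    w <- stats::runif(1, cfg$seg_width[1], cfg$seg_width[2])
    s <- stats::runif(1, 0, 360)
    arts <- c(arts, list(artifact_spec("segmentation", rvisit(),
      region = c(s, (s + w) %% 360),
      magnitude = sample(c(-1, 1), 1L) * stats::runif(1, cfg$seg_magnitude[1], cfg$seg_magnitude[2]))))
  }
  if (stats::runif(1) < cfg$clip_prevalence) {
    w <- stats::runif(1, cfg$clip_width[1], cfg$clip_width[2])
    s <- stats::runif(1, 0, 360)
    arts <- c(arts, list(artifact_spec("clipping", rvisit(),
                                       region = c(s, (s + w) %% 360))))
  }
  if (stats::runif(1) < cfg$scaling_prevalence)
    arts <- c(arts, list(artifact_spec("scaling", rvisit(),
      magnitude = stats::runif(1, -cfg$scaling_max, cfg$scaling_max))))
  if (stats::runif(1) < cfg$rotation_prevalence)
    arts <- c(arts, list(artifact_spec("rotation", "followup",
      magnitude = sample(c(-1, 1), 1L) * stats::runif(1, 1, cfg$rotation_max))))
  arts
}

#' Simulate a labeled cohort of paired-visit eyes
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is bit-identical given the seed.
#' @return List of `eye_record`s, with attribute `injection_summary`
#'   (a `data.frame` of injected factor counts).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n_total <- config$n_P + config$n_NP
  labels <- c(rep("P", config$n_P), rep("NP", config$n_NP))
  specs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    specs[[i]] <- list(
      lesions = if (labels[i] == "P") list(draw_lesion(config)) else list(),
      artifacts = draw_artifacts(config))
  }
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  cohort <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cohort[[i]] <- simulate_pair(config$model, specs[[i]]$lesions,
                                 specs[[i]]$artifacts, seed = sub_seeds[i],
                                 eye_id = sprintf("eye%03d", i), n = config$n)
  }
  kinds <- unlist(lapply(cohort, function(e)
    vapply(e$artifacts, `[[`, "", "kind")))
  tab <- table(factor(kinds, levels = c("segmentation", "schisis", "clipping",
                                        "scaling", "rotation")))
  attr(cohort, "injection_summary") <- data.frame(
    factor = names(tab), count = as.integer(tab),
    prevalence = as.numeric(tab) / n_total)
  attr(cohort, "seed") <- seed
  cohort
}

#' Simulate artifact-free no-change test-retest pairs
#'
#' Used to calibrate and fit the quantile-regression cutoff.  Baseline G
#' values are spread uniformly over `g_range`.
#'
#' @param model A [normative_model()].
#' @param n_pairs Number of pairs (>= 2).
#' @param seed Integer seed.
#' @param g_range Range of baseline G values to cover, um.
#' @param n Grid size.
#' @return List of [visit_pair()] objects.
#' @export
simulate_testretest <- function(model, n_pairs, seed = 1L,
                                g_range = c(60, 110), n = 768L) {
  if (n_pairs < 2) abort_param("need at least 2 test-retest pairs")
  set.seed(seed)
  targets <- stats::runif(n_pairs, g_range[1], g_range[2])
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  lapply(seq_len(n_pairs), function(i)
    simulate_pair(model, seed = sub_seeds[i],
                  eye_id = sprintf("rt%05d", i),
                  g_target = targets[i], n = n)$pair)
}
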