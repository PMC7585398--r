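# Rule-based post hoc grading of defects and scan artifacts:
#   - local (< 45 deg) vs widespread (>= 90 deg below-band) defect rules,
#   - segmentation-error regions (graded when wider than 5 deg),
#   - alignment check via vessel-shadow landmarks,
#   - apparent-scaling (multiplicative) estimation,
#   - clipping detection,
#   - per-cause factor ranking of a simulated eye's delta-G.

#' Empirical normative bands from the healthy generator
#'
#' Per-sample 5th- and 1st-percentile thickness curves over simulated
#' healthy eyes, standing in for a device normative database.
#'
#' @param model A [normative_model()].
#' @param n_eyes Number of simulated healthy profiles.
#' @param seed Integer seed.
#' @param n Grid size.
#' @return A `normative_bands` object with fields `p5`, `p1`, `mean`.
#' @export
normative_bands <- function(model, n_eyes = 2000L, seed = 1L, n = 768L) {
  stopifnot(inherits(model, "normative_model"))
  set.seed(seed)
  shape <- mean_shape(model, n)
  mat <- matrix(0, n_eyes, n)
  for (i in seq_len(n_eyes)) {
    offset <- if (model$between_eye_sd > 0) stats::rnorm(1, 0, model$between_eye_sd) else 0
    mat[i, ] <- pmax(shape + offset + visit_noise(model, n), 0)
  }
  structure(list(
    p5 = apply(mat, 2, stats::quantile, probs = 0.05, names = FALSE),
    p1 = apply(mat, 2, stats::quantile, probs = 0.01, names = FALSE),
    mean = colMeans(mat), n_eyes = n_eyes),
    class = "normative_bands")
}

classify_run_width <- function(width_deg, below_band_width_deg) {
  if (width_deg < 45) "local"
  else if (below_band_width_deg >= 90) "widespread"
  else "intermediate"
}

#' Detect progression-like defect regions on a visit pair
#'
#' Maximal contiguous runs where follow-up thickness is below
#' `baseline - depth_min` AND below the 5th-percentile normative band.
#' Runs separated by gaps narrower than `merge_gap` are merged.  A run is
#' classified `local` when narrower than 45 degrees; `widespread` when the
#' containing below-band run (regardless of `depth_min`) spans at least 90
#' degrees; `intermediate` otherwise.
#'
#' @param pair A [visit_pair()].
#' @param bands A [normative_bands()] on the same grid.
#' @param depth_min Minimum follow-up-minus-baseline loss, um.
#' @param merge_gap Gap-merging width, degrees.
#' @return `data.frame` with columns `start_deg`, `end_deg`, `width_deg`,
#'   `mean_depth_um`, `classification`.
#' @export
detect_defects <- function(pair, bands, depth_min = 5, merge_gap = 5) {
  stopifnot(inherits(pair, "visit_pair"), inherits(bands, "normative_bands"))
  n <- length(pair$baseline$angles)
  if (length(bands$p5) != n) abort_param("bands and pair must share the grid")
  angles <- pair$baseline$angles
  step <- 360 / n
  drop_mask <- pair$followup$thickness < pair$baseline$thickness - depth_min
  below_band <- pair$followup$thickness < bands$p5
  runs <- merge_runs(circular_runs(drop_mask & below_band, angles),
                     merge_gap, n, angles)
  below_runs <- circular_runs(below_band, angles)
  out <- data.frame(start_deg = numeric(0), end_deg = numeric(0),
                    width_deg = numeric(0), mean_depth_um = numeric(0),
                    classification = character(0))
  for (i in seq_len(nrow(runs))) {
    idx <- run_indices(runs$start_idx[i], runs$end_idx[i], n)
    # widest below-band run overlapping this defect run
    bb_width <- 0
    for (j in seq_len(nrow(below_runs))) {
      jdx <- run_indices(below_runs$start_idx[j], below_runs$end_idx[j], n)
      if (length(intersect(idx, jdx)) > 0)
        bb_width <- max(bb_width, below_runs$width_deg[j])
    }
    out <- rbind(out, data.frame(
      start_deg = runs$start_deg[i],
      end_deg = (runs$start_deg[i] + runs$width_deg[i]) %% 360,
      width_deg = runs$width_deg[i],
      mean_depth_um = mean(pair$baseline$thickness[idx] -
                             pair$followup$thickness[idx]),
      classification = classify_run_width(runs$width_deg[i], bb_width)))
  }
  out
}

#' Grade segmentation-error regions of a simulated eye
#'
#' Compares each visit's measured profile against the latent truth and
#' reports maximal runs where the absolute error exceeds `tol`, kept only
#' when wider than 5 degrees (the grading rule).  Clipped samples are
#' excluded (clipping is graded separately).
#'
#' @param record An `eye_record` with latent truth.
#' @param tol Error tolerance, um (> 0).
#' @return `data.frame` with columns `visit`, `start_deg`, `end_deg`,
#'   `width_deg`, `mean_error_um` (signed).
#' @export
grade_segmentation <- function(record, tol = 5) {
  if (!inherits(record, "eye_record") || is.null(record$latent_baseline))
    abort_unsupported("grade_segmentation needs a simulated eye with latent truth")
  if (tol <= 0) abort_param("tol must be > 0")
  out <- data.frame(visit = character(0), start_deg = numeric(0),
                    end_deg = numeric(0), width_deg = numeric(0),
                    mean_error_um = numeric(0))
  for (visit in c("baseline", "followup")) {
    obs <- record$pair[[visit]]
    latent <- if (visit == "baseline") record$latent_baseline else record$latent_followup
    err <- obs$thickness - latent$thickness
    mask <- abs(err) > tol & obs$valid
    runs <- circular_runs(mask, obs$angles)
    runs <- runs[runs$width_deg > 5, , drop = FALSE]
    n <- length(obs$angles)
    for (i in seq_len(nrow(runs))) {
      idx <- run_indices(runs$start_idx[i], runs$end_idx[i], n)
      out <- rbind(out, data.frame(
        visit = visit, start_deg = runs$start_deg[i],
        end_deg = (runs$start_deg[i] + runs$width_deg[i]) %% 360,
        width_deg = runs$width_deg[i], mean_error_um = mean(err[idx])))
    }
  }
  out
}

# Signed circular difference in (-180, 180].
circ_signed_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Check scan alignment via vessel-shadow landmarks
#'
#' Each baseline vessel marker is matched to the nearest follow-up marker;
#' the scan is deemed misaligned when the median absolute per-vessel shift
#' exceeds the median vessel-shadow width.
#'
#' @param pair A [visit_pair()] whose profiles carry vessel markers.
#' @return List with `misaligned` (logical) and `shift_deg` (median signed
#'   shift, degrees).
#' @export
check_alignment <- function(pair) {
  stopifnot(inherits(pair, "visit_pair"))
  vb <- pair$baseline$vessels
  vf <- pair$followup$vessels
  if (!nrow(vb) || !nrow(vf))
    abort_unsupported("both visits need at least one vessel marker")
  shifts <- vapply(seq_len(nrow(vb)), function(i) {
    d <- circ_signed_diff(vf$center_deg, vb$center_deg[i])
    d[which.min(abs(d))]
  }, 0)
  shadow <- stats::median(c(vb$shadow_width_deg, vf$shadow_width_deg))
  list(misaligned = stats::median(abs(shifts)) > shadow,
       shift_deg = stats::median(shifts))
}

#' Estimate an apparent multiplicative thickness change between visits
#'
#' Least-squares estimate of `s` in `T_followup ~ (1 + s) * T_baseline`,
#' over samples valid on both visits and outside `exclude_regions` (known
#' or detected defect/segmentation regions).  On noiseless proportional
#' profiles this is exactly the ratio estimator.
#'
#' @param pair A [visit_pair()].
#' @param exclude_regions Optional list of `c(start_deg, end_deg)` arcs.
#' @param s_flag Flag threshold on |s| (default 0.02, below the ~5% ceiling
#'   such artifacts reach).
#' @return List with `s` (fraction) and `flagged` (logical).
#' @export
estimate_scaling <- function(pair, exclude_regions = NULL, s_flag = 0.02) {
  stopifnot(inherits(pair, "visit_pair"))
  keep <- pair$baseline$valid & pair$followup$valid
  for (reg in exclude_regions) {
    width <- (reg[2] - reg[1]) %% 360
    if (width == 0) width <- 360
    keep <- keep & !in_arc(pair$baseline$angles, reg[1], width)
  }
  n <- length(keep)
  if (sum(keep) < n / 2)
    abort_unsupported("fewer than 50% of samples usable for scaling estimate")
  tb <- pair$baseline$thickness[keep]
  tf <- pair$followup$thickness[keep]
  s <- sum(tb * tf) / sum(tb * tb) - 1
  list(s = s, flagged = abs(s) >= s_flag)
}

#' Detect clipped regions of a profile
#'
#' Maximal runs where the validity mask is FALSE or thickness has collapsed
#' to at most `clip_floor`, kept when at least `clip_min_deg` wide.
#'
#' @param profile A [thickness_profile()].
#' @param clip_floor Collapse threshold, um.
#' @param clip_min_deg Minimum reported width, degrees.
#' @return `data.frame` with columns `start_deg`, `end_deg`, `width_deg`.
#' @export
detect_clipping <- function(profile, clip_floor = 10, clip_min_deg = 10) {
  mask <- !profile$valid | profile$thickness <= clip_floor
  runs <- circular_runs(mask, profile$angles)
  runs <- runs[runs$width_deg >= clip_min_deg, , drop = FALSE]
  data.frame(start_deg = runs$start_deg,
             end_deg = (runs$start_deg + runs$width_deg) %% 360,
             width_deg = runs$width_deg)
}

#' Full grading report with per-cause factor ranking
#'
#' Combines the ground-truth delta-G decomposition with the measured-side
#' detectors and ranks the contributing causes by absolute delta-G
#' contribution (rank 1 = primary), mirroring the primary/secondary factor
#' notation of clinical grading tables.  Residual noise is not ranked.
#'
#' @param record An `eye_record` with latent truth.
#' @param bands Optional [normative_bands()] for defect detection.
#' @param min_contribution Smallest |contribution| (um) a cause needs to be
#'   ranked.
#' @return A `grading_report`: fields `eye_id`, `defects`,
#'   `segmentation_regions`, `alignment`, `scaling`, `clipped_regions`,
#'   `factor_ranking` (`data.frame(cause, contribution_um, rank)`).
#' @export
attribute_factors <- function(record, bands = NULL, min_contribution = 0.05) {
  decomp <- decompose_delta_g(record)
  causes <- decomp[decomp$cause != "noise", , drop = FALSE]
  # relabel lesion contributions by lesion kind (local / widespread)
  if (length(record$lesions)) {
    kinds <- vapply(record$lesions, `[[`, "", "kind")
    causes$cause[causes$cause == "lesion"] <- kinds
  }
  agg <- if (nrow(causes))
    stats::aggregate(contribution_um ~ cause, data = causes, FUN = sum)
  else data.frame(cause = character(0), contribution_um = numeric(0))
  agg <- agg[abs(agg$contribution_um) >= min_contribution, , drop = FALSE]
  agg <- agg[order(-abs(agg$contribution_um)), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  structure(list(
    eye_id = record$eye_id,
    defects = if (!is.null(bands)) detect_defects(record$pair, bands) else NULL,
    segmentation_regions = grade_segmentation(record),
    alignment = tryCatch(check_alignment(record$pair),
                         cprnfl_unsupported_error = function(e) NULL),
    scaling = tryCatch(estimate_scaling(record$pair),
                       cprnfl_unsupported_error = function(e) NULL),
    clipped_regions = {
      with_visit <- function(visit, df) {
        df$visit <- rep(visit, nrow(df))
        df
      }
      rbind(with_visit("baseline", detect_clipping(record$pair$baseline)),
            with_visit("followup", detect_clipping(record$pair$followup)))
    },
    factor_ranking = agg, delta_g = record$pair$delta_g),
    class = "grading_report")
}

#' @export
print.grading_report <- function(x, ...) {
  cat(sprintf("<grading_report> %s: dG = %+.2f um\n", x$eye_id, x$delta_g))
  if (nrow(x$factor_ranking)) {
    for (i in seq_len(nrow(x$factor_ranking)))
      cat(sprintf("  %d. %-12s %+.2f um\n", x$factor_ranking$rank[i],
                  x$factor_ranking$cause[i], x$factor_ranking$contribution_um[i]))
  } else cat("  no ranked factors\n")
  invisible(x)
}
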