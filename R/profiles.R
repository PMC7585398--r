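# Core containers: circumpapillary thickness profiles and visit pairs.
#
# A profile lives on a fixed uniform angular grid over [0, 360).  The
# canonical grid has 768 samples (360/768 = 0.46875 degrees per step,
# exactly representable in binary), matching typical circle-scan A-scan
# counts.  Angle 0 is the temporal meridian, increasing through superior;
# profiles are in right-eye canonical orientation.

#' Canonical angular grid
#'
#' @param n Number of samples per 360 degrees.
#' @return Numeric vector of angles in degrees, `[0, 360)`, uniform.
#' @export
profile_grid <- function(n = 768L) {
  n <- as.integer(n)
  if (is.na(n) || n < 90L) abort_param("grid size must be an integer >= 90")
  (seq_len(n) - 1L) * (360 / n)
}

#' Construct a circumpapillary thickness profile
#'
#' @param thickness Thickness in micrometers per angular sample, >= 0.
#' @param angles Angular grid in degrees; must be uniform over `[0, 360)`.
#' @param valid Logical validity mask (FALSE marks samples excluded by the
#'   device, e.g. clipped A-scans).
#' @param vessels `data.frame` with columns `center_deg`, `shadow_width_deg`
#'   giving blood-vessel shadow landmarks.
#' @param eye_id,visit Optional identifiers used by the CSV writer.
#' @return An object of class `thickness_profile`.
#' @export
thickness_profile <- function(thickness,
                              angles = profile_grid(length(thickness)),
                              valid = rep(TRUE, length(thickness)),
                              vessels = empty_vessels(),
                              eye_id = NA_character_,
                              visit = NA_character_) {
  thickness <- as.numeric(thickness)
  angles <- as.numeric(angles)
  valid <- as.logical(valid)
  if (length(angles) != length(thickness) || length(valid) != length(thickness))
    abort_param("angles, thickness and valid must have equal length")
  check_uniform_grid(angles)
  if (any(!is.finite(thickness[valid])))
    abort_param("thickness must be finite where valid")
  if (!is.data.frame(vessels) ||
      !all(c("center_deg", "shadow_width_deg") %in% names(vessels)))
    abort_param("vessels must have columns center_deg, shadow_width_deg")
  structure(
    list(angles = angles, thickness = thickness, valid = valid,
         vessels = vessels, eye_id = eye_id, visit = visit),
    class = "thickness_profile")
}

empty_vessels <- function() {
  data.frame(center_deg = numeric(0), shadow_width_deg = numeric(0))
}

check_uniform_grid <- function(angles) {
  n <- length(angles)
  if (n < 2L) abort_param("profile needs at least 2 samples")
  step <- 360 / n
  expected <- (seq_len(n) - 1L) * step
  if (max(abs(angles - expected)) > 1e-9)
    abort_param("angles must be the uniform grid (i * 360/n, i = 0..n-1)")
  invisible(step)
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("<thickness_profile> %d samples, mean %.2f um, %d invalid, %d vessels\n",
              length(x$angles), mean(x$thickness), sum(!x$valid), nrow(x$vessels)))
  invisible(x)
}

#' Pair of baseline and follow-up profiles for one eye
#'
#' `delta_g` is follow-up G minus baseline G; negative values indicate
#' thinning (loss).
#'
#' @param eye_id Eye identifier.
#' @param baseline,followup `thickness_profile` objects on the same grid.
#' @param invalid_policy Passed to [global_mean()] when deriving G values.
#' @return An object of class `visit_pair` with fields `g_baseline`,
#'   `g_followup`, `delta_g`.
#' @export
visit_pair <- function(eye_id, baseline, followup,
                       invalid_policy = c("include_measured", "exclude")) {
  invalid_policy <- match.arg(invalid_policy)
  stopifnot(inherits(baseline, "thickness_profile"),
            inherits(followup, "thickness_profile"))
  if (length(baseline$angles) != length(followup$angles) ||
      max(abs(baseline$angles - followup$angles)) > 1e-9)
    abort_param("baseline and followup must share the same angular grid")
  gb <- global_mean(baseline, invalid_policy)
  gf <- global_mean(followup, invalid_policy)
  structure(
    list(eye_id = eye_id, baseline = baseline, followup = followup,
         g_baseline = gb, g_followup = gf, delta_g = gf - gb,
         invalid_policy = invalid_policy),
    class = "visit_pair")
}

#' @export
print.visit_pair <- function(x, ...) {
  cat(sprintf("<visit_pair> %s: G %.2f -> %.2f um, dG = %+.2f um\n",
              x$eye_id, x$g_baseline, x$g_followup, x$delta_g))
  invisible(x)
}

# ---- circular geometry helpers ------------------------------------------

#' Circular distance between angles, in degrees (range 0 to 180)
#' @param a,b Angles in degrees.
#' @keywords internal
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Half-open circular arc membership: angle in [start, start + width), wrap OK.
in_arc <- function(angles, start, width) {
  if (width <= 0) return(rep(FALSE, length(angles)))
  if (width >= 360) return(rep(TRUE, length(angles)))
  ((angles - start) %% 360) < width
}

# Maximal circular runs of TRUE in a logical mask.  Returns a data.frame
# with 1-based sample indices (end may be < start when the run wraps) and
# angular start/width.  A run covering the whole circle is one row.
circular_runs <- function(mask, angles) {
  n <- length(mask)
  step <- 360 / n
  if (!any(mask))
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_deg = numeric(0), width_deg = numeric(0)))
  if (all(mask))
    return(data.frame(start_idx = 1L, end_idx = n,
                      start_deg = angles[1L], width_deg = 360))
  k <- which(!mask)[1L]                      # rotate so position 1 is FALSE
  ord <- c(k:n, seq_len(k - 1L))
  r <- rle(mask[ord])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  start_idx <- ord[starts[keep]]
  end_idx <- ord[ends[keep]]
  data.frame(start_idx = start_idx, end_idx = end_idx,
             start_deg = angles[start_idx],
             width_deg = r$lengths[keep] * step)
}

# Merge circular runs separated by gaps smaller than merge_gap degrees.
merge_runs <- function(runs, merge_gap, n, angles) {
  if (nrow(runs) <= 1L) return(runs)
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(runs))) {
    idx <- run_indices(runs$start_idx[i], runs$end_idx[i], n)
    mask[idx] <- TRUE
  }
  gap_samples <- max(0L, ceiling(merge_gap / (360 / n)) - 1L)
  if (gap_samples > 0L) {
    gaps <- circular_runs(!mask, angles)
    for (i in seq_len(nrow(gaps))) {
      idx <- run_indices(gaps$start_idx[i], gaps$end_idx[i], n)
      if (length(idx) < n && length(idx) * (360 / n) < merge_gap) mask[idx] <- TRUE
    }
  }
  circular_runs(mask, angles)
}

# Expand a (start_idx, end_idx) circular run into sample indices.
run_indices <- function(start_idx, end_idx, n) {
  if (end_idx >= start_idx) start_idx:end_idx
  else c(start_idx:n, seq_len(end_idx))
}

# ---- condition helpers ---------------------------------------------------

abort_param <- function(msg) {
  stop(errorCondition(msg, class = c("cprnfl_parameter_error", "cprnfl_error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("cprnfl_format_error", "cprnfl_error")))
}

abort_unsupported <- function(msg) {
  stop(errorCondition(msg, class = c("cprnfl_unsupported_error", "cprnfl_error")))
}

abort_value <- function(msg) {
  stop(errorCondition(msg, class = c("cprnfl_value_error", "cprnfl_error")))
}
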