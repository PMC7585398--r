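# Profile metrics: the G metric, sector means, delta-G, and the
# region-wise area-between-curves decomposition of delta-G.
#
# Quadrature convention: on the uniform grid, G is the plain mean of the
# samples and a region's contribution is sum(difference over region)/n.
# Using the same convention everywhere makes conservation (sectors or any
# region partition recombining to G / delta-G) exact by construction.

#' Global mean cpRNFL thickness (the G metric)
#'
#' @param profile A [thickness_profile()].
#' @param invalid_policy `"include_measured"` (default) averages the
#'   measured values even where the validity mask is FALSE — this mirrors
#'   device behavior in which clipped regions corrupt the reported G.
#'   `"exclude"` drops invalid samples.
#' @return Mean thickness in micrometers.
#' @export
global_mean <- function(profile, invalid_policy = c("include_measured", "exclude")) {
  invalid_policy <- match.arg(invalid_policy)
  x <- profile$thickness
  if (invalid_policy == "exclude") {
    x <- x[profile$valid]
    if (length(x) == 0L) abort_value("all samples excluded; G undefined")
  }
  mean(x)
}

#' Sector scheme for pie-chart style sector means
#'
#' The default is a device-style six-sector scheme: temporal T `[315,45)`,
#' temporal-superior TS `[45,90)`, nasal-superior NS `[90,135)`, nasal N
#' `[135,225)`, nasal-inferior NI `[225,270)`, temporal-inferior TI
#' `[270,315)`.
#'
#' @param sectors `data.frame` with columns `label`, `start_deg`, `end_deg`
#'   (half-open arcs, may wrap); must partition the circle exactly.
#' @return A `sector_scheme` object.
#' @export
sector_scheme <- function(sectors = default_sectors()) {
  if (!is.data.frame(sectors) ||
      !all(c("label", "start_deg", "end_deg") %in% names(sectors)))
    abort_param("sectors must have columns label, start_deg, end_deg")
  widths <- (sectors$end_deg - sectors$start_deg) %% 360
  widths[widths == 0] <- 360
  if (abs(sum(widths) - 360) > 1e-9)
    abort_param("sectors must partition [0, 360): widths sum to 360")
  sectors$width_deg <- widths
  structure(sectors, class = c("sector_scheme", "data.frame"))
}

default_sectors <- function() {
  data.frame(
    label = c("T", "TS", "NS", "N", "NI", "TI"),
    start_deg = c(315, 45, 90, 135, 225, 270),
    end_deg = c(45, 90, 135, 225, 270, 315))
}

#' Per-sector mean thickness
#'
#' Sector means recombine to the global mean: `sum(width/360 * mean)` equals
#' [global_mean()] exactly (same quadrature).
#'
#' @param profile A [thickness_profile()].
#' @param scheme A [sector_scheme()].
#' @param invalid_policy See [global_mean()].
#' @return Named numeric vector of sector means (micrometers).
#' @export
sector_means <- function(profile, scheme = sector_scheme(),
                         invalid_policy = c("include_measured", "exclude")) {
  invalid_policy <- match.arg(invalid_policy)
  if (!inherits(scheme, "sector_scheme")) scheme <- sector_scheme(scheme)
  n <- length(profile$angles)
  assign_count <- rep(0L, n)
  out <- numeric(nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    sel <- in_arc(profile$angles, scheme$start_deg[i], scheme$width_deg[i])
    assign_count[sel] <- assign_count[sel] + 1L
    x <- profile$thickness[sel]
    if (invalid_policy == "exclude") x <- x[profile$valid[sel]]
    out[i] <- mean(x)
  }
  if (any(assign_count != 1L))
    abort_param("sector scheme does not partition the grid (gap or overlap)")
  names(out) <- scheme$label
  out
}

#' Change in global thickness for a visit pair
#'
#' @param pair A [visit_pair()].
#' @return `g_followup - g_baseline` in micrometers (negative = loss).
#' @export
delta_g <- function(pair) {
  stopifnot(inherits(pair, "visit_pair"))
  pair$delta_g
}

#' Signed contribution of an angular region to delta-G
#'
#' The area between the follow-up and baseline curves over the region,
#' normalized by the full circle: `sum(T_f - T_b over region)/n`.  Over any
#' partition of the circle the contributions sum to `delta_g` exactly.
#'
#' @param pair A [visit_pair()].
#' @param region Numeric `c(start_deg, end_deg)`, half-open, may wrap.
#' @return Contribution in micrometers.
#' @export
region_contribution <- function(pair, region) {
  stopifnot(inherits(pair, "visit_pair"))
  width <- (region[2] - region[1]) %% 360
  if (width == 0 && region[2] != region[1]) width <- 360
  if (width == 0) return(0)
  sel <- in_arc(pair$baseline$angles, region[1], width)
  sum(pair$followup$thickness[sel] - pair$baseline$thickness[sel]) /
    length(pair$baseline$angles)
}

#' Cause-tagged decomposition of delta-G for a simulated eye
#'
#' Replays the ground-truth construction of a simulated eye (lesions, then
#' per-visit artifacts, then noise) and reports the change in G contributed
#' by each cause.  Baseline-visit effects enter with a minus sign (they
#' shift `g_baseline`).  The tagged contributions telescope, so they sum to
#' the observed `delta_g` to machine precision.  The `lesion` rows equal the
#' delta-G that would be observed with perfect segmentation and no
#' artifacts.
#'
#' @param record An `eye_record` from [simulate_pair()] or
#'   [simulate_cohort()]; must carry latent truth.
#' @return `data.frame` with columns `cause` (`lesion`, `segmentation`,
#'   `scaling`, `alignment`, `clipping`, `noise`), `visit`, `start_deg`,
#'   `end_deg`, `contribution_um`; attribute `delta_g`.
#' @export
decompose_delta_g <- function(record) {
  if (!inherits(record, "eye_record") || is.null(record$latent_baseline))
    abort_unsupported("decompose_delta_g needs a simulated eye with latent truth")
  rows <- list()
  add <- function(cause, visit, start_deg, end_deg, contribution) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cause = cause, visit = visit, start_deg = start_deg,
      end_deg = end_deg, contribution_um = contribution)
  }

  # lesion terms: sequential application to the latent baseline
  prof <- record$latent_baseline
  for (les in record$lesions) {
    nxt <- apply_lesion(prof, les)
    add("lesion", "followup",
        (les$center_deg - les$width_deg / 2) %% 360,
        (les$center_deg + les$width_deg / 2) %% 360,
        mean(nxt$thickness) - mean(prof$thickness))
    prof <- nxt
  }

  # artifact + noise terms per visit, via the shared construction chain
  for (visit in c("baseline", "followup")) {
    sign <- if (visit == "baseline") -1 else 1
    latent <- if (visit == "baseline") record$latent_baseline else record$latent_followup
    noise <- if (visit == "baseline") record$noise_baseline else record$noise_followup
    arts <- Filter(function(a) a$visit == visit, record$artifacts)
    trace <- apply_visit_effects(latent, arts, noise, trace = TRUE)$trace
    for (tr in trace) {
      cause <- switch(tr$kind,
                      segmentation = "segmentation", schisis = "segmentation",
                      scaling = "scaling", rotation = "alignment",
                      clipping = "clipping", noise = "noise")
      add(cause, visit, tr$start_deg, tr$end_deg, sign * tr$dG)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cause = character(0), visit = character(0),
               start_deg = numeric(0), end_deg = numeric(0),
               contribution_um = numeric(0))
  attr(out, "delta_g") <- record$pair$delta_g
  out
}
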