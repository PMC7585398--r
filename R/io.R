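# File formats, packaged fixtures, and the end-to-end pipeline.
#
# Profile CSV dialect (frozen): comma separator, dot decimal, LF line
# endings, UTF-8, header `eye_id,visit,angle_deg,thickness_um,valid,
# vessel_marker`, one row per grid sample, visits named baseline/followup.
# Values are written at full precision so write/read round-trips are
# lossless.

FIXTURE_FILES <- c(
  table1 = "table1_criterion_sweep.csv",
  table2 = "table2_fp_eyes.csv",
  table3 = "table3_fn_eyes.csv",
  table4 = "table4_extreme_eyes.csv")

FIXTURE_MD5 <- c(
  table1 = "dcfbbead46323405eb85dda67e829fb5",
  table2 = "34ee432a03f82d17a61c182b92b6a137",
  table3 = "cd52b765fc09bfb9c138dd2ce8b38989",
  table4 = "2795fd8c7be7b4af90c72959290c1e69")

FIXTURE_ROWS <- c(table1 = 7L, table2 = 5L, table3 = 16L, table4 = 6L)

#' Load a packaged reference table
#'
#' The packaged fixtures hold the published criterion sweep (table1), the
#' five FP eyes (table2), the sixteen FN eyes (table3) and the six
#' extreme-delta-G eyes (table4), with per-eye delta-G values and factor
#' ranks.  File checksums and row counts are verified on load.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return A `data.frame`.
#' @export
load_fixture <- function(table_id = c("table1", "table2", "table3", "table4")) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", FIXTURE_FILES[[table_id]], package = "cprnfl")
  if (!nzchar(path)) abort_format(sprintf("fixture %s not installed", table_id))
  if (unname(tools::md5sum(path)) != FIXTURE_MD5[[table_id]])
    abort_format(sprintf("fixture %s failed its checksum", table_id))
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(out) != FIXTURE_ROWS[[table_id]])
    abort_format(sprintf("fixture %s has %d rows, expected %d",
                         table_id, nrow(out), FIXTURE_ROWS[[table_id]]))
  out
}

profile_to_rows <- function(profile) {
  marker <- rep(0L, length(profile$angles))
  for (i in seq_len(nrow(profile$vessels))) {
    w <- profile$vessels$shadow_width_deg[i]
    sel <- in_arc(profile$angles, profile$vessels$center_deg[i] - w / 2, w)
    marker[sel] <- 1L
  }
  data.table::data.table(
    eye_id = profile$eye_id, visit = profile$visit,
    angle_deg = profile$angles, thickness_um = profile$thickness,
    valid = as.integer(profile$valid), vessel_marker = marker)
}

#' Write profiles to the canonical CSV format
#'
#' @param profiles A list of [thickness_profile()] objects (each carrying
#'   `eye_id` and `visit`), a single profile, a [visit_pair()], or a list
#'   of pairs / `eye_record`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  profiles <- flatten_profiles(profiles)
  rows <- data.table::rbindlist(lapply(profiles, profile_to_rows))
  data.table::setorder(rows, eye_id, visit, angle_deg)   # canonical order
  data.table::fwrite(rows, path, eol = "\n")
  invisible(path)
}

flatten_profiles <- function(x) {
  if (inherits(x, "thickness_profile")) return(list(x))
  if (inherits(x, "visit_pair")) {
    b <- x$baseline; f <- x$followup
    b$eye_id <- f$eye_id <- x$eye_id
    b$visit <- "baseline"; f$visit <- "followup"
    return(list(b, f))
  }
  if (inherits(x, "eye_record")) return(flatten_profiles(x$pair))
  if (is.list(x)) return(do.call(c, lapply(x, flatten_profiles)))
  abort_param("cannot interpret input as profiles")
}

#' Read profiles from the canonical CSV format
#'
#' @param path CSV path in the documented dialect.
#' @return List of [thickness_profile()] objects (one per eye/visit),
#'   with vessel markers reconstructed from the marker runs.
#' @export
read_profiles <- function(path) {
  required <- c("eye_id", "visit", "angle_deg", "thickness_um", "valid",
                "vessel_marker")
  dt <- data.table::fread(path, colClasses = list(character = c("eye_id", "visit")))
  if (!all(required %in% names(dt)))
    abort_format(sprintf("missing columns: %s",
                         paste(setdiff(required, names(dt)), collapse = ", ")))
  if (nrow(dt) == 0L) {
    warning("profile file has a header but no rows")
    return(list())
  }
  dt$`.row` <- seq_len(nrow(dt)) + 1L   # file line numbers (header = 1)
  groups <- split(dt, list(dt$eye_id, dt$visit), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$angle_deg), ]
    dup <- duplicated(g$angle_deg)
    if (any(dup))
      abort_format(sprintf("duplicate (eye, visit, angle) at row %d",
                           g$`.row`[which(dup)[1]]))
    n <- nrow(g)
    expected <- (seq_len(n) - 1L) * (360 / n)
    bad <- which(abs(g$angle_deg - expected) > 1e-6)
    if (length(bad))
      abort_format(sprintf("non-uniform angle grid at row %d (angle %g)",
                           g$`.row`[bad[1]], g$angle_deg[bad[1]]))
    runs <- circular_runs(g$vessel_marker > 0, g$angle_deg)
    vessels <- if (nrow(runs))
      data.frame(center_deg = (runs$start_deg + runs$width_deg / 2) %% 360,
                 shadow_width_deg = runs$width_deg)
    else empty_vessels()
    thickness_profile(g$thickness_um, angles = g$angle_deg,
                      valid = g$valid > 0, vessels = vessels,
                      eye_id = g$eye_id[1], visit = g$visit[1])
  })
  names(out) <- NULL
  out
}

#' Per-eye metrics table for a cohort
#'
#' @param cohort List of `eye_record`s or [visit_pair()]s.
#' @return `data.frame` with columns `eye_id`, `label` (if available),
#'   `g_baseline`, `g_followup`, `delta_g`.
#' @export
cohort_metrics <- function(cohort) {
  rows <- lapply(cohort, function(e) {
    pair <- if (inherits(e, "eye_record")) e$pair else e
    data.frame(eye_id = pair$eye_id,
               label = if (inherits(e, "eye_record")) e$truth_label else NA_character_,
               g_baseline = pair$g_baseline, g_followup = pair$g_followup,
               delta_g = pair$delta_g)
  })
  do.call(rbind, rows)
}

#' Run the full simulate / classify / grade / evaluate pipeline
#'
#' Stages: simulate a labeled cohort, write profile and per-eye metrics
#' CSVs, fit the QR cutoff on internally simulated test-retest pairs,
#' sweep the criteria, grade every eye, and record a manifest (seed,
#' config hash, package version).  Reruns with the same config and seed
#' are bit-identical.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; substreams for the cohort and the QR
#'   calibration set are derived from it.
#' @param criteria_um Fixed cutoffs to sweep, um.
#' @param n_qr Test-retest pairs for the QR fit.
#' @return Invisibly, a list with `cohort`, `metrics`, `sweep`, `grading`,
#'   `qr_model`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = 1L,
                         criteria_um = 3:8, n_qr = 500L) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  seed_cohort <- seed
  seed_qr <- (seed + 104729L) %% .Machine$integer.max   # named substream

  cohort <- simulate_cohort(config, seed_cohort)
  write_profiles(cohort, file.path(out_dir, "profiles.csv"))
  metrics <- cohort_metrics(cohort)
  data.table::fwrite(metrics, file.path(out_dir, "metrics.csv"), eol = "\n")

  rt <- simulate_testretest(config$model, n_qr, seed_qr, n = config$n)
  qr_model <- fit_qr(rt)
  write_qr_model(qr_model, file.path(out_dir, "qr_model.json"))

  criteria <- c(lapply(criteria_um, fixed_cutoff), list(qr_model))
  sweep <- if (config$n_P + config$n_NP > 0)
    sweep_criteria(metrics, criteria) else NULL
  if (!is.null(sweep))
    data.table::fwrite(sweep, file.path(out_dir, "sweep.csv"), eol = "\n")

  grading <- data.table::rbindlist(lapply(cohort, function(e) {
    rep <- attribute_factors(e)
    if (!nrow(rep$factor_ranking))
      return(data.table::data.table(eye_id = e$eye_id, cause = "none",
                                    rank = NA_integer_, contribution_um = 0))
    data.table::data.table(eye_id = e$eye_id, cause = rep$factor_ranking$cause,
                           rank = rep$factor_ranking$rank,
                           contribution_um = rep$factor_ranking$contribution_um)
  }))
  data.table::fwrite(grading, file.path(out_dir, "grading.csv"), eol = "\n")

  cfg_json <- config_to_json(config)
  manifest <- list(
    seed = seed, seed_cohort = seed_cohort, seed_qr = seed_qr,
    config_md5 = as.character(tools::md5sum(cfg_json)),
    package_version = as.character(utils::packageVersion("cprnfl")),
    n_eyes = length(cohort),
    injection_summary = attr(cohort, "injection_summary"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(cohort = cohort, metrics = metrics, sweep = sweep,
                 grading = as.data.frame(grading), qr_model = qr_model,
                 manifest = manifest))
}

# Serialize the config (model flattened) to a temp JSON file; returns path.
config_to_json <- function(config) {
  x <- unclass(config)
  x$model <- unclass(x$model)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  path
}
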