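# Statistical progression criteria: fixed delta-G cutoffs and the
# quantile-regression (QR) event cutoff fitted on no-change test-retest
# pairs.
#
# The QR cutoff follows the event-analysis convention used by perimetry
# and OCT progression software: regress follow-up G on baseline G, take a
# lower conditional quantile (default tau = 0.05, i.e. the 95th percentile
# of loss), and use the distance from the identity line as the
# baseline-dependent progression cutoff.

#' Fixed delta-G cutoff criterion
#'
#' @param c_um Loss magnitude in um that triggers a progression flag (> 0).
#'   `c_um = 5` is the informal clinical "rule of 5".
#' @return A `fixed_cutoff` object.
#' @export
fixed_cutoff <- function(c_um) {
  if (!is.finite(c_um) || c_um <= 0) abort_param("cutoff must be > 0")
  structure(list(c_um = c_um), class = c("fixed_cutoff", "criterion_model"))
}

#' Flag progression under a fixed cutoff
#'
#' The boundary is inclusive: an eye is flagged iff `delta_g <= -c`.
#'
#' @param delta_g Delta-G in um (follow-up minus baseline).
#' @param cutoff A [fixed_cutoff()] or a positive number.
#' @return Logical vector.
#' @export
flag_fixed <- function(delta_g, cutoff) {
  if (is.numeric(cutoff)) cutoff <- fixed_cutoff(cutoff)
  stopifnot(inherits(cutoff, "fixed_cutoff"))
  if (any(!is.finite(delta_g))) abort_param("delta_g must be finite")
  delta_g <= -cutoff$c_um
}

# Check loss rho_tau(u) = u * (tau - 1[u < 0]).
check_loss <- function(u, tau) sum(u * (tau - (u < 0)))

#' Fit the quantile-regression cutoff model
#'
#' Minimizes the check loss `sum(rho_tau(y - a - b x))` for the affine
#' conditional quantile of follow-up G (`y`) given baseline G (`x`), by
#' iteratively reweighted least squares with a small residual floor.  The
#' fit is deterministic for a fixed input ordering.
#'
#' @param pairs Either a list of [visit_pair()] objects or a `data.frame`
#'   with columns `g_baseline`, `g_followup`; at least 20 pairs.
#' @param tau Quantile level in (0, 1); default 0.05 (the 95th percentile
#'   of loss).
#' @param max_iter,tol IRLS iteration controls.
#' @return A `qr_cutoff_model` with fields `tau`, `intercept`, `slope`.
#'   The progression cutoff at baseline `g` is
#'   `cutoff(g) = intercept + slope * g - g`.
#' @export
fit_qr <- function(pairs, tau = 0.05, max_iter = 200L, tol = 1e-12) {
  if (is.list(pairs) && !is.data.frame(pairs) &&
      all(vapply(pairs, inherits, TRUE, "visit_pair"))) {
    pairs <- data.frame(
      g_baseline = vapply(pairs, `[[`, 0, "g_baseline"),
      g_followup = vapply(pairs, `[[`, 0, "g_followup"))
  }
  if (!all(c("g_baseline", "g_followup") %in% names(pairs)))
    abort_param("pairs must provide g_baseline and g_followup")
  if (nrow(pairs) < 20L) abort_param("QR fit needs at least 20 pairs")
  if (tau <= 0 || tau >= 1) abort_param("tau must be in (0, 1)")
  x <- pairs$g_baseline
  y <- pairs$g_followup
  if (stats::sd(x) < 1e-12) abort_param("degenerate design: baseline G constant")
  X <- cbind(1, x)
  beta <- stats::coef(stats::lm.fit(X, y))
  eps <- 1e-6
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    w <- abs(tau - (r < 0)) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, as.numeric(w))
    new_beta <- stats::coef(fit)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  structure(list(tau = tau, intercept = unname(beta[1]),
                 slope = unname(beta[2]), n = nrow(pairs)),
            class = c("qr_cutoff_model", "criterion_model"))
}

#' Baseline-dependent progression cutoff of a QR model
#'
#' @param model A fitted `qr_cutoff_model`.
#' @param g_baseline Baseline G values, um.
#' @return Cutoff in um (typically negative): flag iff `delta_g <= cutoff`.
#' @export
qr_cutoff <- function(model, g_baseline) {
  stopifnot(inherits(model, "qr_cutoff_model"))
  model$intercept + model$slope * g_baseline - g_baseline
}

#' Flag progression under a QR cutoff model
#'
#' Inclusive boundary: flagged iff `delta_g <= cutoff(g_baseline)`.
#'
#' @param pair A [visit_pair()], or a `data.frame` with columns `delta_g`
#'   and `g_baseline`.
#' @param model A fitted `qr_cutoff_model`.
#' @return Logical vector.
#' @export
flag_qr <- function(pair, model) {
  if (!inherits(model, "qr_cutoff_model") || is.null(model$intercept))
    abort_param("model must be a fitted qr_cutoff_model")
  if (inherits(pair, "visit_pair"))
    pair <- data.frame(delta_g = pair$delta_g, g_baseline = pair$g_baseline)
  pair$delta_g <= qr_cutoff(model, pair$g_baseline)
}

#' @export
print.qr_cutoff_model <- function(x, ...) {
  cat(sprintf("<qr_cutoff_model> tau = %.3f, followup = %.3f + %.4f * baseline (n = %d)\n",
              x$tau, x$intercept, x$slope, x$n))
  cat(sprintf("  cutoff at G_b = 70: %+.2f um; at G_b = 100: %+.2f um\n",
              qr_cutoff(x, 70), qr_cutoff(x, 100)))
  invisible(x)
}

#' Serialize / restore a QR cutoff model as JSON
#'
#' @param model A `qr_cutoff_model`.
#' @param path File path.
#' @return `read_qr_model` returns the restored model.
#' @export
write_qr_model <- function(model, path) {
  stopifnot(inherits(model, "qr_cutoff_model"))
  jsonlite::write_json(list(tau = model$tau, intercept = model$intercept,
                            slope = model$slope, n = model$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qr_model
#' @export
read_qr_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("tau", "intercept", "slope") %in% names(x)))
    abort_format("QR model JSON must have fields tau, intercept, slope")
  structure(list(tau = x$tau, intercept = x$intercept, slope = x$slope,
                 n = if (is.null(x$n)) NA_integer_ else x$n),
            class = c("qr_cutoff_model", "criterion_model"))
}
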