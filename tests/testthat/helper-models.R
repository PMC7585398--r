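# Shared builders for the test suite.

# Flat model: constant profile at base_level, no peaks, no vessels, no noise.
flat_model <- function(base_level = 80) {
  normative_model(
    base_level = base_level,
    peaks = data.frame(center_deg = numeric(0), amplitude_um = numeric(0),
                       width_deg = numeric(0)),
    vessels = data.frame(center_deg = numeric(0), amplitude_um = numeric(0),
                         width_deg = numeric(0), shadow_width_deg = numeric(0)),
    between_eye_sd = 0, within_eye_profile_sd = 0, g_retest_sd = 0)
}

# Default shape with all noise switched off.
quiet_model <- function() {
  normative_model(between_eye_sd = 0, within_eye_profile_sd = 0, g_retest_sd = 0)
}

constant_profile <- function(value = 80, n = 768L, ...) {
  thickness_profile(rep(value, n), ...)
}

# Independent half-open arc membership used as a brute-force oracle.
in_arc_test <- function(angles, start, width) {
  ((angles - start) %% 360) < width
}

# Profile with vessel markers at given centers (constant thickness).
marked_profile <- function(centers, shadow_width = 3, value = 80, n = 768L) {
  thickness_profile(rep(value, n),
                    vessels = data.frame(center_deg = centers,
                                         shadow_width_deg = shadow_width))
}
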