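#' @name scenarios
#' @title Reference experiment scenarios
#'
#' @description
#' Frozen simulator configurations used by the package's validation
#' experiments. Each function returns [breathing_params()] for one scenario;
#' the scenario definitions (not just the seeds) are part of the package's
#' documented study conditions.
NULL

#' Noise-floor recovery scenario
#'
#' Affine coupling with zero phase lag and no hysteresis (so the
#' external-internal relation is exactly affine), 0.5 mm X-ray localization
#' noise, and the longest clinical training regime (27 imaging points over
#' 603 s). With these conditions the only irreducible error at validation
#' imaging points is the localization noise itself, whose 3-D RMSE floor is
#' sigma * sqrt(3).
#'
#' @param seed RNG seed.
#' @return A [breathing_params()] object (duration 603 s).
#' @export
noise_floor_params <- function(seed = 1) {
  breathing_params(seed = seed, duration = 603, lag = 0, hysteresis = 0,
                   internal_noise_sd = 0.5,
                   coupling = default_affine_coupling())
}

#' Planted-FCM two-regime scenario
#'
#' A constructed case in which the external-to-internal coupling is
#' two-regime piecewise linear (hinge on the superior-inferior driver) with
#' low localization noise, slow baseline drift, and few training points —
#' the regime structure plus end-of-training drift is captured best by the
#' FCM-refined fuzzy partition, making FCM-FIS the planted best candidate
#' for model selectivity.
#'
#' @param seed RNG seed.
#' @return A [breathing_params()] object (duration 300 s; pair with 8
#'   imaging points).
#' @export
planted_fcm_params <- function(seed = 1) {
  base <- default_affine_coupling()
  coup <- coupling_piecewise(base$A, base$b, gain = c(0.3, 1.2, 5),
                             driver = c(0, 0, 1, 0, 0, 1, 0, 0, 1) / 3,
                             threshold_quantile = 0.6)
  breathing_params(seed = seed, duration = 300, lag = 0,
                   internal_noise_sd = 0.2, period_jitter_sd = 0.2,
                   amplitude_jitter_sd = 0.1, drift_rate = 1,
                   coupling = coup)
}

#' Drifting-patient scenario for model updating
#'
#' Affine coupling with a pronounced baseline drift: a model trained early in
#' the session degrades as the baseline moves, so rebuilding on accumulated
#' imaging data should recover accuracy on the following minute.
#'
#' @param seed RNG seed.
#' @return A [breathing_params()] object (duration 420 s).
#' @export
drifting_params <- function(seed = 1) {
  breathing_params(seed = seed, duration = 420, lag = 0,
                   internal_noise_sd = 0.3,
                   drift_rate = c(0.3, 0.8, 1.5, 0.3, 0.6, 1.2, 0.2, 0.5, 1.0),
                   coupling = default_affine_coupling())
}
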