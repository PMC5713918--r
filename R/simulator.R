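#' @name simulator
#' @title Synthetic respiratory-motion simulator
#'
#' @description
#' Generates correlated external-marker (9-channel) and internal-tumor
#' (3-channel) trajectories standing in for proprietary clinical tracking
#' logs. Breathing is a quasi-periodic cosine-power (Lujan-type) waveform
#' with cycle-to-cycle period and amplitude jitter, baseline drift,
#' observation noise, an external-internal phase lag, optional hysteresis
#' (different inhale/exhale internal path), and a configurable
#' external-to-internal coupling (affine, two-regime piecewise linear, or
#' sigmoidal saturation). All traces are synthetic and fully reproducible
#' from a seed.
NULL

# Run expr with a seeded RNG, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a bounded sub-seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483647
}

#' Affine external-to-internal coupling
#'
#' @param A 3 x 9 matrix mapping external channels (mm) to internal position.
#' @param b Length-3 offset (mm).
#' @return Coupling spec of class `coupling_spec`.
#' @export
coupling_affine <- function(A, b = c(0, 0, 0)) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == 3L, ncol(A) == 9L, length(b) == 3L)
  structure(list(type = "affine", A = A, b = as.numeric(b)),
            class = "coupling_spec")
}

#' Two-regime piecewise-linear coupling
#'
#' A continuous piecewise-linear (hinge) map: the base affine response plus
#' an extra per-axis slope on a scalar driver (a projection of the external
#' channels) beyond a quantile threshold of its own trajectory,
#' y = A x + b + gain * max(0, d - thr). A stylization of depth-dependent
#' organ mechanics that a single linear map cannot represent.
#'
#' @param A,b Base affine map (3 x 9 matrix, length-3 offset, mm).
#' @param gain Length-3 extra slope per mm of driver beyond the threshold.
#' @param driver Length-9 projection vector defining the driver signal.
#' @param threshold_quantile Quantile of the driver at which the regime
#'   switches.
#' @return Coupling spec of class `coupling_spec`.
#' @export
coupling_piecewise <- function(A, b, gain,
                               driver = c(0, 0, 1, 0, 0, 0, 0, 0, 0),
                               threshold_quantile = 0.5) {
  structure(list(type = "piecewise", A = as.matrix(A), b = as.numeric(b),
                 gain = as.numeric(gain), driver = as.numeric(driver),
                 threshold_quantile = threshold_quantile),
            class = "coupling_spec")
}

#' Sigmoidal saturation coupling
#'
#' Internal motion saturates at deep inhale/exhale:
#' y = b + gain * tanh((driver . x - center) / width) per axis.
#'
#' @param gain Length-3 per-axis gain (mm).
#' @param b Length-3 offset (mm).
#' @param driver Length-9 projection vector.
#' @param center,width Location and softness of the saturation, in driver
#'   units (mm).
#' @return Coupling spec of class `coupling_spec`.
#' @export
coupling_sigmoid <- function(gain, b = c(0, 0, 0),
                             driver = c(0, 0, 1, 0, 0, 0, 0, 0, 0),
                             center = 0, width = 3) {
  structure(list(type = "sigmoid", gain = as.numeric(gain), b = as.numeric(b),
                 driver = as.numeric(driver), center = center, width = width),
            class = "coupling_spec")
}

apply_coupling <- function(coupling, S) {
  switch(coupling$type,
         affine = sweep(tcrossprod(S, coupling$A), 2L, coupling$b, "+"),
         piecewise = {
           d <- as.vector(S %*% coupling$driver)
           thr <- stats::quantile(d, coupling$threshold_quantile, names = FALSE)
           hinge <- pmax(d - thr, 0)
           sweep(tcrossprod(S, coupling$A), 2L, coupling$b, "+") +
             outer(hinge, coupling$gain)
         },
         sigmoid = {
           d <- as.vector(S %*% coupling$driver)
           act <- tanh((d - coupling$center) / coupling$width)
           sweep(outer(act, coupling$gain), 2L, coupling$b, "+")
         },
         stop("unknown coupling type"))
}

# Default affine coupling: internal motion dominated by SI, driven mostly by
# the markers' SI/AP channels, with amplitude amplification typical of
# abdominal surrogates vs lung tumors.
default_affine_coupling <- function() {
  A <- matrix(0, 3, 9)
  # channels: m1(x,y,z) m2(x,y,z) m3(x,y,z); x = LR, y = AP, z = SI
  A[1, c(1, 4, 7)] <- c(0.3, 0.2, 0.1)                 # internal LR
  A[2, c(2, 5, 8)] <- c(0.5, 0.3, 0.2)                 # internal AP
  A[3, c(3, 6, 9)] <- c(1.0, 0.6, 0.4)                 # internal SI
  coupling_affine(A, b = c(2, -5, 40))
}

#' Breathing simulation parameters
#'
#' Defaults describe a mild, regular breather: 4 s mean period, small
#' cycle-to-cycle jitter, marker oscillation amplitudes of a few mm (largest
#' in AP/SI), sub-mm optical tracking noise, 0.5 mm X-ray localization noise,
#' and a 0.2 s external-internal phase lag.
#'
#' @param period_mean Mean breathing period tau (s).
#' @param period_jitter_sd SD of the cycle-wise period (s).
#' @param amplitudes Length-9 oscillation amplitude per external channel (mm),
#'   ordered m1(x,y,z), m2(x,y,z), m3(x,y,z).
#' @param amplitude_jitter_sd Fractional SD of the cycle-wise amplitude.
#' @param shape_n Cosine-power exponent: waveform cos^(2n)(phase/2); larger n
#'   gives longer end-exhale dwell.
#' @param baseline Length-9 resting position per external channel (mm).
#' @param drift_rate Length-9 (or scalar) baseline drift (mm/min).
#' @param external_noise_sd Optical tracking noise SD (mm).
#' @param internal_noise_sd X-ray localization noise SD (mm), applied to
#'   imaging observations.
#' @param lag External-internal phase lag (s); internal motion follows the
#'   surface by this delay.
#' @param hysteresis Dimensionless inhale/exhale path separation; 0 = none.
#' @param coupling A `coupling_spec`; default a fixed affine map.
#' @param duration Simulation length (s).
#' @param rate External sampling rate (Hz).
#' @param seed RNG seed.
#' @return A list of class `breathing_params`.
#' @export
breathing_params <- function(period_mean = 4, period_jitter_sd = 0.2,
                             amplitudes = c(1.5, 8, 4, 1, 6, 3, 0.8, 5, 2.5),
                             amplitude_jitter_sd = 0.05,
                             shape_n = 2,
                             baseline = c(20, 50, 100, -30, 60, 150, 10, 40, 200),
                             drift_rate = 0,
                             external_noise_sd = 0.1,
                             internal_noise_sd = 0.5,
                             lag = 0.2,
                             hysteresis = 0,
                             coupling = default_affine_coupling(),
                             duration = 300, rate = 25, seed = 1) {
  if (period_mean <= 0 || duration <= 0 || rate <= 0) {
    stop("period, duration and rate must be positive")
  }
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (length(drift_rate) == 1L) drift_rate <- rep(drift_rate, 9L)
  structure(list(period_mean = period_mean, period_jitter_sd = period_jitter_sd,
                 amplitudes = amplitudes,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 shape_n = shape_n, baseline = baseline,
                 drift_rate = drift_rate,
                 external_noise_sd = external_noise_sd,
                 internal_noise_sd = internal_noise_sd,
                 lag = lag, hysteresis = hysteresis, coupling = coupling,
                 duration = duration, rate = rate, seed = seed),
            class = "breathing_params")
}

# Phase/amplitude profile over a time grid: phase advances 2*pi per jittered
# cycle; amplitude factor is redrawn per cycle.
breathing_phase <- function(params, t_max) {
  periods <- numeric(0); amps <- numeric(0)
  total <- 0
  while (total < t_max + 2 * params$period_mean) {
    p <- max(0.3 * params$period_mean,
             stats::rnorm(1, params$period_mean, params$period_jitter_sd))
    periods <- c(periods, p)
    amps <- c(amps, max(0, 1 + stats::rnorm(1, 0, params$amplitude_jitter_sd)))
    total <- total + p
  }
  starts <- cumsum(c(0, periods[-length(periods)]))
  phase_at <- function(t) {
    k <- findInterval(t, starts)
    2 * pi * (k - 1) + 2 * pi * (t - starts[k]) / periods[k]
  }
  amp_at <- function(t) amps[findInterval(t, starts)]
  list(phase_at = phase_at, amp_at = amp_at)
}

#' Simulate one synthetic patient
#'
#' Produces the dense external trace (observed, with optical noise), the
#' dense noiseless internal-truth trajectory (the coupling applied to the
#' lag-shifted latent surface signal, plus the hysteresis term), and a
#' default sparse imaging training set.
#'
#' @param params A [breathing_params()].
#' @param n_imaging Number of imaging points in the bundled training set.
#' @param schedule Imaging schedule passed to [sample_imaging()].
#' @return An object of class `sim_patient` with components `external`
#'   (9-channel `marker_trace`), `internal_truth` (3-channel, noiseless),
#'   `imaging` (`training_set`), `latent` (noiseless external), and `params`.
#' @export
simulate_patient <- function(params = breathing_params(), n_imaging = 10,
                             schedule = "uniform") {
  with_seed(params$seed, {
    t <- seq(0, params$duration, by = 1 / params$rate)
    prof <- breathing_phase(params, params$duration)
    phase <- prof$phase_at(t)
    ampf <- prof$amp_at(t)
    ch_off <- seq(0, 0.4, length.out = 9L)   # small fixed per-channel phase offsets
    osc <- vapply(seq_len(9L), function(c) {
      params$amplitudes[c] * ampf * cos(phase / 2 + ch_off[c])^(2 * params$shape_n)
    }, numeric(length(t)))
    drift <- outer(t / 60, params$drift_rate)
    latent <- sweep(osc + drift, 2L, params$baseline, "+")

    # lag-shifted latent signal evaluated analytically at t - lag
    tl <- pmax(t - params$lag, 0)
    phase_l <- prof$phase_at(tl)
    ampf_l <- prof$amp_at(tl)
    osc_l <- vapply(seq_len(9L), function(c) {
      params$amplitudes[c] * ampf_l * cos(phase_l / 2 + ch_off[c])^(2 * params$shape_n)
    }, numeric(length(t)))
    latent_l <- sweep(osc_l + outer(tl / 60, params$drift_rate), 2L,
                      params$baseline, "+")

    truth <- apply_coupling(params$coupling, latent_l)
    if (params$hysteresis != 0) {
      # inhale/exhale path separation: an odd-in-phase offset (with a 3rd
      # harmonic, so it is not an affine shadow of the surface channels)
      osc_sd <- apply(truth, 2L, stats::sd)
      truth <- truth + params$hysteresis * outer(sin(phase_l)^3, osc_sd)
    }

    ext_noise <- matrix(stats::rnorm(length(latent), 0, params$external_noise_sd),
                        nrow = nrow(latent))
    external <- marker_trace(t, latent + ext_noise, sample_rate_hint = params$rate)
    internal_truth <- marker_trace(t, truth, sample_rate_hint = params$rate)

    patient <- structure(
      list(external = external, internal_truth = internal_truth,
           latent = marker_trace(t, latent, sample_rate_hint = params$rate),
           params = params),
      class = "sim_patient")
    patient$imaging <- sample_imaging(patient, n_imaging, schedule = schedule,
                                      seed = derive_seed(params$seed, 1))
    patient
  })
}

#' @export
print.sim_patient <- function(x, ...) {
  cat(sprintf("sim_patient: %.0f s at %g Hz, coupling %s, %d imaging points\n",
              x$params$duration, x$params$rate, x$params$coupling$type,
              n_points(x$imaging)))
  invisible(x)
}

#' Sample sparse imaging observations from a simulated patient
#'
#' Draws `n_points` imaging instants over the simulation window (clinical
#' regimes range from 4 points over 58 s up to 27 points over 603 s), adds
#' X-ray localization noise to the internal truth, and pairs each observation
#' with the linearly interpolated external row at the same instant.
#'
#' @param patient A `sim_patient`.
#' @param n_points Number of imaging points (>= 4 for selectivity use).
#' @param schedule One of "uniform", "random", "burst" (dense early imaging,
#'   then sparse).
#' @param seed RNG seed for imaging times and noise.
#' @param window Optional c(start, end) restricting imaging to a sub-window
#'   of the simulation (s).
#' @return A `training_set`.
#' @export
sample_imaging <- function(patient, n_points, schedule = c("uniform", "random", "burst"),
                           seed = 1, window = NULL) {
  schedule <- match.arg(schedule)
  t <- patient$external$timestamps
  if (is.null(window)) window <- c(t[1], t[length(t)])
  if (n_points > length(t)) stop("n_points exceeds the number of dense samples")
  if (n_points < 1L) stop("n_points must be positive")
  with_seed(seed, {
    span <- window[2] - window[1]
    ts <- switch(schedule,
      uniform = seq(window[1], window[2], length.out = n_points),
      random = sort(window[1] + span * sort(stats::runif(n_points))),
      burst = {
        n_burst <- ceiling(n_points / 2)
        c(seq(window[1], window[1] + 0.2 * span, length.out = n_burst),
          seq(window[1] + 0.3 * span, window[2],
              length.out = n_points - n_burst))
      })
    ts <- sort(ts)
    # enforce strict ordering with at least one sample-period spacing
    eps <- 1 / patient$params$rate
    for (i in seq_along(ts)[-1]) if (ts[i] <= ts[i - 1]) ts[i] <- ts[i - 1] + eps
    ts <- pmin(ts, window[2])
    ts <- ts + 0  # keep numeric
    interp_rows <- function(trace, at) {
      vapply(seq_len(ncol(trace$values)), function(c) {
        stats::approx(trace$timestamps, trace$values[, c], xout = at,
                      rule = 2)$y
      }, numeric(length(at)))
    }
    X <- interp_rows(patient$external, ts)
    Ytrue <- interp_rows(patient$internal_truth, ts)
    noise <- matrix(stats::rnorm(length(Ytrue), 0,
                                 patient$params$internal_noise_sd),
                    nrow = nrow(Ytrue))
    training_set(matrix(X, ncol = 9), matrix(Ytrue + noise, ncol = 3), ts)
  })
}

#' Named parameter presets for the synthetic cohort
#'
#' `control`: mild cycle jitter, no drift, affine coupling, no hysteresis —
#' an easy case for any correlation model. `worst`: strong cycle jitter,
#' baseline drift, nonlinear coupling and hysteresis — the difficult regime
#' where model choice matters. Mirroring the inter-patient variability that
#' motivates per-patient model selection, the worst preset draws its
#' structural parameters (coupling family and strength, drift magnitude,
#' hysteresis, period jitter) per patient from documented ranges, seeded
#' deterministically from `seed`.
#'
#' @param name "control" or "worst".
#' @param seed RNG seed (also seeds the per-patient structural draw).
#' @param duration Simulation length (s).
#' @return A [breathing_params()] object.
#' @export
preset_params <- function(name = c("control", "worst"), seed = 1,
                          duration = 300) {
  name <- match.arg(name)
  if (name == "control") {
    breathing_params(period_jitter_sd = 0.15, amplitude_jitter_sd = 0.04,
                     drift_rate = 0, hysteresis = 0,
                     coupling = default_affine_coupling(),
                     duration = duration, seed = seed)
  } else {
    base <- default_affine_coupling()
    pars <- with_seed(derive_seed(seed, 99), {
      list(type = sample(c("piecewise", "sigmoid"), 1),
           gain_si = stats::runif(1, 2.5, 5),
           drift_scale = stats::runif(1, 0.5, 1.5),
           hysteresis = stats::runif(1, 0.1, 0.4),
           period_jitter = stats::runif(1, 0.4, 0.8))
    })
    coup <- if (pars$type == "piecewise") {
      # deep-inhale regime: SI and AP response steepens beyond the threshold
      coupling_piecewise(base$A, base$b,
                         gain = c(0.5, pars$gain_si / 2, pars$gain_si),
                         driver = c(0, 0, 1, 0, 0, 1, 0, 0, 1) / 3,
                         threshold_quantile = 0.6)
    } else {
      # saturating SI response around the mid-breathing driver position
      coupling_sigmoid(gain = c(2, 5, 12), b = base$b + c(2, 25, 110),
                       driver = c(0, 0, 1, 0, 0, 1, 0, 0, 1) / 3,
                       center = 152, width = 2)
    }
    breathing_params(period_jitter_sd = pars$period_jitter,
                     amplitude_jitter_sd = 0.15,
                     drift_rate = pars$drift_scale *
                       c(0.3, 0.8, 1.5, 0.3, 0.6, 1.2, 0.2, 0.5, 1.0),
                     hysteresis = pars$hysteresis, lag = 0.35,
                     coupling = coup, duration = duration, seed = seed)
  }
}

#' Generate a reproducible synthetic cohort
#'
#' @param presets Character vector of preset names (one patient per entry),
#'   e.g. `rep(c("control", "worst"), each = 10)`.
#' @param seeds Integer seeds, one per patient; default derived from `seed`.
#' @param seed Base seed used when `seeds` is NULL.
#' @param duration Simulation length per patient (s).
#' @param n_imaging Imaging points per patient.
#' @return List of `sim_patient` objects; each carries its preset name in
#'   `$preset`.
#' @export
make_cohort <- function(presets = rep(c("control", "worst"), each = 10),
                        seeds = NULL, seed = 1, duration = 300,
                        n_imaging = 12) {
  if (is.null(seeds)) {
    seeds <- vapply(seq_along(presets), function(i) derive_seed(seed, i),
                    numeric(1))
  }
  stopifnot(length(seeds) == length(presets))
  lapply(seq_along(presets), function(i) {
    p <- simulate_patient(preset_params(presets[i], seed = seeds[i],
                                        duration = duration),
                          n_imaging = n_imaging)
    p$preset <- presets[i]
    p
  })
}
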