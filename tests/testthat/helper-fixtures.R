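# Shared fixtures built in code at test time.

# Training set whose outputs are an exact affine function of the inputs,
# with breathing-like inputs from the simulator (zero noise, zero lag).
make_linear_patient <- function(seed = 1, n_imaging = 27, duration = 300,
                                noise = 0, A = NULL, b = NULL) {
  set.seed(seed * 13 + 1)
  if (is.null(A)) A <- matrix(stats::rnorm(27), 3, 9)
  if (is.null(b)) b <- stats::rnorm(3)
  pat <- simulate_patient(
    breathing_params(seed = seed, duration = duration, lag = 0,
                     hysteresis = 0, external_noise_sd = 0,
                     internal_noise_sd = noise,
                     coupling = coupling_affine(A, b)),
    n_imaging = n_imaging)
  pat$A <- A; pat$b <- b
  pat
}

# Small arbitrary training set (not linearly coupled) for generic fitting.
make_toy_train <- function(n = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n * 9), n, 9)
  Y <- cbind(sin(2 * X[, 1]) + X[, 5],
             X[, 2]^2 - X[, 7],
             tanh(3 * X[, 3]) + 0.2 * X[, 9])
  training_set(X, Y, seq_len(n))
}

# A hand-built single-output rule base with d inputs and R rules.
make_rule_base <- function(R = 3, d = 9, seed = 1, fitted = TRUE) {
  set.seed(seed)
  centers <- matrix(stats::runif(R * d), R, d)
  sigmas <- matrix(stats::runif(R * d, 0.1, 0.5), R, d)
  rb <- rule_base(centers, sigmas)
  if (fitted) {
    rb$coef <- matrix(stats::rnorm(R * d), R, d)
    rb$intercept <- stats::rnorm(R)
  }
  rb
}
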