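#' ANFIS training configuration
#'
#' @param epochs Number of hybrid-learning epochs (>= 0). 0 returns the
#'   subtractive-clustering initialization unchanged.
#' @param initial_step Initial premise step length in normalized units.
#' @param step_increase Factor applied after 4 consecutive error decreases.
#' @param step_decrease Factor applied after an up-down error oscillation.
#' @param radius Subtractive influence range for the initialization.
#' @return A list of class `anfis_config`.
#' @export
anfis_config <- function(epochs = 20L, initial_step = 0.01,
                         step_increase = 1.1, step_decrease = 0.9,
                         radius = 1 / 3) {
  if (epochs < 0L) stop("epochs must be >= 0")
  if (initial_step < 0 || step_increase <= 0 || step_decrease <= 0) {
    stop("step factors must be positive and initial_step non-negative (0 freezes premises)")
  }
  structure(list(epochs = as.integer(epochs), initial_step = initial_step,
                 step_increase = step_increase, step_decrease = step_decrease,
                 radius = radius),
            class = "anfis_config")
}

# Analytic gradient of the summed squared error of one rule base with respect
# to its premise parameters, consequents held fixed. The collapsed Sugeno
# forward pass gives, with S = sum_k w_k and normalized weights wbar:
#   dE/dc_jd     = sum_t 2 e_t (F_tj - f_t) wbar_tj (x_td - c_jd) / sigma_jd^2
#   dE/dsigma_jd = sum_t 2 e_t (F_tj - f_t) wbar_tj (x_td - c_jd)^2 / sigma_jd^3
anfis_premise_gradient <- function(rb, X, y) {
  X <- as.matrix(X)
  R <- n_rules(rb); d <- rb$input_dim
  wbar <- normalized_weights_batch(firing_strengths_batch(rb, X))
  Fmat <- tcrossprod(X, rb$coef) + matrix(rb$intercept, nrow(X), R, byrow = TRUE)
  f <- rowSums(wbar * Fmat)
  e <- f - y
  common <- 2 * e * (Fmat - f) * wbar          # n x R
  g_c <- matrix(0, R, d); g_s <- matrix(0, R, d)
  for (j in seq_len(R)) {
    Dev <- sweep(X, 2L, rb$centers[j, ], "-")  # n x d
    g_c[j, ] <- colSums(common[, j] * Dev) / rb$sigmas[j, ]^2
    g_s[j, ] <- colSums(common[, j] * Dev^2) / rb$sigmas[j, ]^3
  }
  list(centers = g_c, sigmas = g_s, sse = sum(e^2))
}

# One normalized-length gradient descent step on a rule base's premises.
anfis_step_premises <- function(rb, X, y, step) {
  g <- anfis_premise_gradient(rb, X, y)
  gv <- c(g$centers, g$sigmas)
  nrm <- sqrt(sum(gv^2))
  if (!is.finite(nrm)) {
    rb$sigmas[] <- pmax(rb$sigmas, SIGMA_FLOOR)   # sigma underflow guard
    attr(rb, "gradient_event") <- TRUE
    return(rb)
  }
  if (nrm > 0) {
    rb$centers <- rb$centers - step * g$centers / nrm
    rb$sigmas <- rb$sigmas - step * g$sigmas / nrm
  }
  rb$sigmas[] <- pmax(rb$sigmas, SIGMA_FLOOR)
  rb
}

training_rmse_mm <- function(model, train) {
  pred <- predict(model, train$X)
  sqrt(mean(rowSums((pred - train$Y)^2)))
}

#' Train an adaptive neuro-fuzzy inference system (ANFIS)
#'
#' Hybrid learning on the five-layer Sugeno network: the model is initialized
#' by [build_sub_fis()] (subtractive clustering fixes the rules and Gaussian
#' premise parameters); each epoch then (forward) re-solves all consequents by
#' the same global least squares and (backward) takes one batch gradient
#' descent step of the current step length on every premise (center, width).
#' The step length follows the classical heuristic: increased by
#' `step_increase` after 4 consecutive error decreases and decreased by
#' `step_decrease` after an up-down oscillation pattern. The returned model is
#' the epoch snapshot (including the initialization) with minimum 3-D training
#' RMSE.
#'
#' @param train A `training_set` (>= 2 points).
#' @param config An [anfis_config()].
#' @return A fitted `correlation_model` of kind "ANFIS" whose
#'   `provenance$history` holds per-epoch training RMSE (mm) and step size.
#' @export
anfis_train <- function(train, config = anfis_config()) {
  stopifnot(inherits(train, "training_set"))
  init <- build_sub_fis(train, radius = config$radius)
  model <- correlation_model("ANFIS", init$rule_bases, init$normalization,
                             provenance = init$provenance)
  spec <- model$normalization
  Xn <- normalize_inputs(spec, train$X)
  Yn <- normalize_outputs(spec, train$Y)

  rmse0 <- training_rmse_mm(model, train)
  best <- model; best_rmse <- rmse0
  step <- config$initial_step
  err_hist <- rmse0
  hist_rmse <- numeric(0); hist_step <- numeric(0)
  events <- 0L

  if (config$epochs > 0L) {
    rbs <- model$rule_bases
    for (ep in seq_len(config$epochs)) {
      for (k in 1:3) {
        rbs[[k]] <- anfis_step_premises(rbs[[k]], Xn, Yn[, k], step)
        if (isTRUE(attr(rbs[[k]], "gradient_event"))) {
          events <- events + 1L
          attr(rbs[[k]], "gradient_event") <- NULL
        }
        rbs[[k]] <- fit_consequents(rbs[[k]], Xn, Yn[, k])
      }
      model$rule_bases <- rbs
      rmse <- training_rmse_mm(model, train)
      err_hist <- c(err_hist, rmse)
      hist_rmse <- c(hist_rmse, rmse)
      hist_step <- c(hist_step, step)
      if (rmse < best_rmse) {
        best_rmse <- rmse
        best <- model
      }
      # step-size heuristic on the error history
      m <- length(err_hist)
      if (m >= 5L) {
        d4 <- diff(err_hist[(m - 4L):m])
        if (all(d4 < 0)) {
          step <- step * config$step_increase
        } else if (d4[1] < 0 && d4[2] > 0 && d4[3] < 0 && d4[4] > 0 ||
                   d4[1] > 0 && d4[2] < 0 && d4[3] > 0 && d4[4] < 0) {
          step <- step * config$step_decrease
        }
      }
    }
  }
  best$provenance$history <- list(rmse = hist_rmse, step = hist_step)
  best$provenance$initial_rmse <- rmse0
  best$provenance$training_rmse <- best_rmse
  best$provenance$gradient_events <- events
  best$provenance$config <- unclass(config)
  best
}

#' Predict with a trained ANFIS model
#'
#' The ANFIS forward pass (layers 1-5) is algebraically the collapsed Sugeno
#' weighted average, so prediction is identical to
#' [predict.correlation_model()].
#'
#' @param model A fitted `correlation_model`.
#' @param x External input: 9-vector or n x 9 matrix (mm).
#' @return n x 3 matrix of internal positions (mm).
#' @export
anfis_predict <- function(model, x) {
  predict(model, x)
}
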