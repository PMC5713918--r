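#' @name fis
#' @title First-order Takagi-Sugeno fuzzy inference
#'
#' @description
#' Rule premises are products of per-dimension Gaussian membership functions;
#' consequents are first-order (affine) functions of the input; the system
#' output is the normalized-firing-strength weighted average of the rule
#' outputs. One single-output rule base is fitted per internal coordinate.
NULL

SIGMA_FLOOR <- 1e-4  # normalized units; keeps singleton-cluster premises regular

#' Gaussian membership function
#'
#' @param center Center c of the membership function (normalized coordinate).
#' @param sigma Width, floored at 1e-4 normalized units.
#' @return A list of class `gaussian_mf`.
#' @export
gaussian_mf <- function(center, sigma) {
  sigma <- max(sigma, SIGMA_FLOOR)
  structure(list(center = center, sigma = sigma), class = "gaussian_mf")
}

#' Evaluate a Gaussian membership function
#'
#' Computes exp(-(x - c)^2 / (2 sigma^2)), a grade in (0, 1].
#'
#' @param mf A [gaussian_mf()].
#' @param x Scalar or vector of evaluation points.
#' @return Membership grades.
#' @export
mf_eval <- function(mf, x) {
  exp(-(x - mf$center)^2 / (2 * mf$sigma^2))
}

#' Construct a single-output Sugeno rule base
#'
#' @param centers R x d matrix of premise centers (normalized input space).
#' @param sigmas R x d matrix of premise widths (floored at 1e-4).
#' @param coef R x d matrix of consequent linear coefficients (may be NA
#'   before fitting).
#' @param intercept Length-R vector of consequent intercepts.
#' @param output Label of the output coordinate ("x", "y" or "z").
#' @return A list of class `rule_base`.
#' @export
rule_base <- function(centers, sigmas, coef = NULL, intercept = NULL,
                      output = "x") {
  centers <- as.matrix(centers); sigmas <- as.matrix(sigmas)
  stopifnot(all(dim(centers) == dim(sigmas)))
  if (nrow(centers) < 1L) stop("rule base needs at least one rule")
  sigmas[] <- pmax(sigmas, SIGMA_FLOOR)
  R <- nrow(centers); d <- ncol(centers)
  if (is.null(coef)) coef <- matrix(NA_real_, R, d)
  if (is.null(intercept)) intercept <- rep(NA_real_, R)
  structure(list(centers = centers, sigmas = sigmas,
                 coef = as.matrix(coef), intercept = as.numeric(intercept),
                 input_dim = d, output = output),
            class = "rule_base")
}

n_rules <- function(rb) nrow(rb$centers)

#' Rule firing strengths
#'
#' The firing strength of rule i at input x is the product (fuzzy AND) of its
#' per-dimension Gaussian membership grades; with Gaussian premises it is
#' strictly positive everywhere.
#'
#' @param rb A `rule_base`.
#' @param x Input vector of length `rb$input_dim` (normalized).
#' @return Vector of per-rule strengths in (0, 1].
#' @export
firing_strengths <- function(rb, x) {
  if (length(x) != rb$input_dim) stop("input dimension mismatch")
  if (!all(is.finite(x))) stop("input must be finite")
  D2 <- sweep(rb$centers, 2L, x, function(c, xx) (xx - c))^2
  exp(-rowSums(D2 / (2 * rb$sigmas^2)))
}

# Vectorized log firing strengths for a batch: X (n x d) -> n x R matrix.
firing_strengths_batch <- function(rb, X) {
  X <- as.matrix(X)
  n <- nrow(X); R <- n_rules(rb)
  logw <- matrix(0, n, R)
  for (j in seq_len(R)) {
    Dev <- sweep(X, 2L, rb$centers[j, ], "-")
    logw[, j] <- -rowSums(sweep(Dev^2, 2L, 2 * rb$sigmas[j, ]^2, "/"))
  }
  logw
}

#' Normalize firing strengths
#'
#' @param w Vector of strictly positive firing strengths.
#' @return w / sum(w), summing to 1.
#' @export
normalize_firing <- function(w) {
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("firing strengths sum to zero; cannot normalize")
  w / s
}

# Row-normalized firing weights from log-strengths, underflow-safe.
normalized_weights_batch <- function(logw) {
  lw <- logw - apply(logw, 1L, max)
  w <- exp(lw)
  w / rowSums(w)
}

#' Sugeno inference for one rule base
#'
#' The system output is the convex combination of the per-rule affine outputs
#' f_i(x) = p_i . x + r0_i weighted by the normalized firing strengths.
#'
#' @param rb A fitted `rule_base`.
#' @param x Input vector (normalized).
#' @return Scalar output (normalized units).
#' @export
infer <- function(rb, x) {
  if (anyNA(rb$coef)) stop("rule base consequents are not fitted")
  # log-domain weights so that inputs far from every premise still infer
  logw <- -rowSums(sweep(rb$centers, 2L, x, function(c, xx) (xx - c))^2 /
                     (2 * rb$sigmas^2))
  w <- exp(logw - max(logw))
  wbar <- w / sum(w)
  f <- as.vector(rb$coef %*% x) + rb$intercept
  sum(wbar * f)
}

# Batch inference: X (n x d) -> length-n outputs.
infer_batch <- function(rb, X) {
  X <- as.matrix(X)
  wbar <- normalized_weights_batch(firing_strengths_batch(rb, X))
  Fmat <- tcrossprod(X, rb$coef) + matrix(rb$intercept, nrow(X), n_rules(rb), byrow = TRUE)
  rowSums(wbar * Fmat)
}

# Minimum-norm least-squares solve via SVD pseudoinverse.
pinv_solve <- function(A, y, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

# Ridge solve with the penalty level chosen by generalized cross-validation
# over a log grid. The grid is floored low enough that exactly representable
# (zero-residual) data select an effectively unpenalized solve, so noiseless
# inputs are reproduced to numerical precision; with noisy, collinear designs
# GCV damps the noise-dominated singular directions.
ridge_gcv_solve <- function(A, y, grid = NULL) {
  n <- nrow(A)
  sv <- svd(A)
  uty <- as.numeric(crossprod(sv$u, y))
  rss0 <- sum(y^2) - sum(uty^2)            # residual outside the column span
  gcv <- function(lambda) {
    shrink <- lambda / (sv$d^2 + lambda)
    rss <- rss0 + sum((shrink * uty)^2)
    edf <- sum(sv$d^2 / (sv$d^2 + lambda))
    n * rss / (n - min(edf, n - 1e-8))^2
  }
  if (is.null(grid)) grid <- sv$d[1]^2 * 10^seq(-16, 0, by = 0.5)
  lambda <- grid[which.min(vapply(grid, gcv, numeric(1)))]
  list(theta = as.numeric(sv$v %*% (sv$d * uty / (sv$d^2 + lambda))),
       lambda = lambda)
}

#' Fit Sugeno consequents by global least squares
#'
#' With premises fixed, the predictor is linear in the consequent parameters:
#' f(x_t) = sum_i wbar_i(x_t) (p_i . x_t + r0_i). All R (d + 1) parameters are
#' estimated jointly by minimizing the summed squared training error, which is
#' exactly the objective used at inference time. When the design is
#' rank-deficient (fewer points than parameters, duplicated rows), a small
#' ridge penalty (lambda = 1e-8) regularizes the solve, shrinking every
#' rule's consequent toward the global first-order fit of y on x rather than
#' toward zero — so the degenerate path reduces gracefully to pooled linear
#' regression and noiseless affine data remain exactly reproduced — and a
#' warning flag is set on the returned rule base.
#'
#' @param rb A `rule_base` with premises set.
#' @param X Training inputs, n x d (normalized).
#' @param y Training outputs, length n (normalized).
#' @return The rule base with `coef`, `intercept`, `residual_rmse` and
#'   `ls_warning` filled in.
#' @export
fit_consequents <- function(rb, X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); d <- rb$input_dim; R <- n_rules(rb)
  if (n < 1L) stop("need at least one training point")
  wbar <- normalized_weights_batch(firing_strengths_batch(rb, X))
  # Design: for rule i, columns wbar_i * [X, 1].
  A <- matrix(0, n, R * (d + 1L))
  for (i in seq_len(R)) {
    cols <- ((i - 1L) * (d + 1L) + 1L):(i * (d + 1L))
    A[, cols] <- wbar[, i] * cbind(X, 1)
  }
  warn <- FALSE
  theta <- tryCatch({
    fit <- qr(A, LAPACK = TRUE)
    if (fit$rank < ncol(A) || n < ncol(A)) stop("rank deficient")
    qr.coef(fit, y)
  }, error = function(e) NULL)
  if (is.null(theta) || anyNA(theta)) {
    warn <- TRUE
    # Global first-order fit as shrinkage target, itself GCV-stabilized (the
    # external channels are strongly collinear, so an unpenalized solve would
    # amplify noise-dominated directions).
    G <- cbind(X, 1)
    theta_g <- ridge_gcv_solve(G, y)$theta
    theta_rep <- rep(theta_g, R)
    resid <- y - as.vector(A %*% theta_rep)
    # Per-rule deviations from the global fit, again with a GCV-chosen ridge
    # (absolute grid floored at 1e-8): zero residual (exactly affine data)
    # gives zero deviation at any level.
    theta <- theta_rep +
      ridge_gcv_solve(A, resid, grid = 10^seq(-8, 2, by = 0.5))$theta
  }
  theta <- as.numeric(theta)
  for (i in seq_len(R)) {
    base <- (i - 1L) * (d + 1L)
    rb$coef[i, ] <- theta[base + seq_len(d)]
    rb$intercept[i] <- theta[base + d + 1L]
  }
  rb$residual_rmse <- sqrt(mean((as.vector(A %*% theta) - y)^2))
  rb$ls_warning <- warn
  rb
}

#' Fitted correlation model
#'
#' Bundle of three single-output Sugeno rule bases (internal x, y, z), the
#' normalization fitted from the training data, and training provenance.
#'
#' @param model_kind One of "SUB_FIS", "FCM_FIS", "ANFIS".
#' @param rule_bases List of 3 fitted `rule_base` objects.
#' @param normalization A `norm_spec`.
#' @param provenance List of training metadata (n_points, radius, ...).
#' @return An object of class `correlation_model`.
#' @export
correlation_model <- function(model_kind, rule_bases, normalization,
                              provenance = list()) {
  model_kind <- match.arg(model_kind, c("SUB_FIS", "FCM_FIS", "ANFIS"))
  if (length(rule_bases) != 3L) stop("exactly 3 rule bases required")
  for (rb in rule_bases) {
    if (!inherits(rb, "rule_base") || n_rules(rb) < 1L) {
      stop("each rule base must hold at least one rule")
    }
  }
  structure(list(model_kind = model_kind, rule_bases = rule_bases,
                 normalization = normalization, provenance = provenance),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("correlation_model: %s, rules per output: %s, trained on %s points\n",
              x$model_kind,
              paste(vapply(x$rule_bases, n_rules, 1L), collapse = "/"),
              x$provenance$n_points %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict internal tumor position from external marker positions
#'
#' @param object A fitted `correlation_model`.
#' @param newdata External inputs: a 9-vector, an n x 9 matrix, or a 9-channel
#'   `marker_trace` (units mm).
#' @param ... Unused.
#' @return An n x 3 matrix of internal positions in mm.
#' @export
predict.correlation_model <- function(object, newdata, ...) {
  if (inherits(newdata, "marker_trace")) newdata <- newdata$values
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(X) != 9L) stop("external input must have 9 channels")
  Xn <- normalize_inputs(object$normalization, X)
  Yn <- vapply(object$rule_bases, function(rb) infer_batch(rb, Xn),
               numeric(nrow(X)))
  Yn <- matrix(Yn, nrow = nrow(X))
  denormalize_outputs(object$normalization, Yn)
}

# sigma from the subtractive radius: the influence-range Gaussian
# exp(-||x-c||^2/(r/2)^2) equals exp(-(x-c)^2/(2 sigma^2)) per dimension at
# sigma = r / sqrt(8); range is 1 in normalized units.
sigma_from_radius <- function(r, range = 1) r * range / sqrt(8)

# Shared builder core: cluster each output's joint (input + output) space,
# derive premises from the input block of each center, fit consequents.
build_fis_core <- function(train, radius, refine, kind, fcm_par = NULL,
                           sub_par = NULL) {
  stopifnot(inherits(train, "training_set"))
  if (n_points(train) < 2L) stop("need at least 2 training points")
  spec <- fit_normalization(train)
  Xn <- normalize_inputs(spec, train$X)
  Yn <- normalize_outputs(spec, train$Y)
  if (is.null(sub_par)) sub_par <- subtractive_params(r = radius)
  labels <- c("x", "y", "z")
  rbs <- vector("list", 3L)
  meta <- list()
  for (k in 1:3) {
    joint <- cbind(Xn, Yn[, k])
    sub <- subtractive_cluster(joint, sub_par)
    if (!refine) {
      centers <- sub$centers[, 1:9, drop = FALSE]
      sigmas <- matrix(sigma_from_radius(radius), nrow(centers), 9L)
      meta[[labels[k]]] <- list(n_clusters = nrow(centers))
    } else {
      C <- nrow(sub$centers)
      fp <- if (is.null(fcm_par)) fcm_params(C) else
        fcm_params(C, m = fcm_par$m, eps = fcm_par$eps,
                   max_iterations = fcm_par$max_iterations)
      res <- fcm(joint, fp, initial_centers = sub$centers)
      centers <- res$centers[, 1:9, drop = FALSE]
      # membership-weighted spread per dimension, floored
      Um <- res$memberships^fp$m
      sigmas <- matrix(0, C, 9L)
      for (j in seq_len(C)) {
        dev2 <- sweep(Xn, 2L, centers[j, ], "-")^2
        sigmas[j, ] <- sqrt(colSums(Um[, j] * dev2) / sum(Um[, j]))
      }
      sigmas[] <- pmax(sigmas, SIGMA_FLOOR)
      meta[[labels[k]]] <- list(n_clusters = C, fcm_iterations = res$iterations)
    }
    rb <- rule_base(centers, sigmas, output = labels[k])
    rbs[[k]] <- fit_consequents(rb, Xn, Yn[, k])
  }
  correlation_model(kind, rbs, spec,
                    provenance = list(n_points = n_points(train),
                                      radius = radius, clustering = meta))
}

#' Build a subtractive-clustering fuzzy inference system (SUB-FIS)
#'
#' For each internal coordinate, the joint normalized (input + output) space
#' is clustered by subtractive clustering; each cluster becomes one rule.
#' Premise centers are the input block of each cluster center; premise widths
#' are (r x data width)/sqrt(8) in normalized units, the width at which the
#' per-dimension Gaussian reproduces the clustering influence range.
#' Consequents are fitted by [fit_consequents()].
#'
#' @param train A `training_set` (>= 2 points).
#' @param radius Influence range as a fraction of data width; default 1/3,
#'   the operating point of the clinical model.
#' @param sub_params Optional full [subtractive_params()]; overrides `radius`.
#' @return A fitted `correlation_model` of kind "SUB_FIS".
#' @export
build_sub_fis <- function(train, radius = 1 / 3, sub_params = NULL) {
  if (!is.null(sub_params)) radius <- sub_params$r
  build_fis_core(train, radius, refine = FALSE, kind = "SUB_FIS",
                 sub_par = sub_params)
}

#' Build a fuzzy C-means fuzzy inference system (FCM-FIS)
#'
#' The cluster count C is fixed by subtractive clustering of the joint space;
#' FCM then refines the centers by fuzzy partitioning. Premise widths are the
#' membership-weighted spread around each refined center,
#' sigma_dj = sqrt(sum_i u_ij^m (x_id - c_jd)^2 / sum_i u_ij^m), floored at
#' 1e-4. Consequents are fitted by [fit_consequents()].
#'
#' @param train A `training_set` (>= 2 points).
#' @param radius Subtractive influence range used to seed C; default 1/3.
#' @param fcm_par Optional [fcm_params()] (its `n_clusters` is overridden by
#'   the subtractive count).
#' @return A fitted `correlation_model` of kind "FCM_FIS".
#' @export
build_fcm_fis <- function(train, radius = 1 / 3, fcm_par = NULL) {
  build_fis_core(train, radius, refine = TRUE, kind = "FCM_FIS",
                 fcm_par = fcm_par)
}
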