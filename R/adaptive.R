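#' Split a training set temporally for model selectivity
#'
#' The available training dataset is divided with a one-fourth ratio: the
#' earliest ceiling(0.75 n) points form the fit set and the remaining (most
#' recent) points the check set. A temporal, not random, split is used because
#' tracking is a forecasting task: the selectivity premise is that the model
#' performing best at the end of training keeps performing best during
#' treatment.
#'
#' @param train A `training_set` with at least 4 points.
#' @param check_fraction Fraction held out for checking (default 0.25).
#' @return List with components `fit` and `check`, both `training_set`s.
#' @export
split_training <- function(train, check_fraction = 0.25) {
  stopifnot(inherits(train, "training_set"))
  n <- n_points(train)
  if (n < 4L) stop("insufficient data for selectivity: need >= 4 points, got ", n)
  n_fit <- ceiling((1 - check_fraction) * n)
  n_fit <- min(max(n_fit, 1L), n - 1L)
  take <- function(idx) training_set(train$X[idx, , drop = FALSE],
                                     train$Y[idx, , drop = FALSE],
                                     train$timestamps[idx])
  list(fit = take(seq_len(n_fit)), check = take((n_fit + 1L):n))
}

#' Candidate model configurations for training and selectivity
#'
#' @param radius Subtractive influence range (fraction of data width).
#' @param fcm_par Optional [fcm_params()] template for FCM-FIS.
#' @param anfis_cfg An [anfis_config()] for ANFIS.
#' @param kinds Candidate kinds to consider, in tie-break priority order.
#'   The default order FCM_FIS, ANFIS, SUB_FIS breaks check-RMSE ties in
#'   favor of FCM-FIS.
#' @param tie_rel Relative check-RMSE difference below which candidates are
#'   considered tied. Check sets hold only 1-7 points, so the standard error
#'   of their RMSE is tens of percent; differences within 1% carry no
#'   evidence and the priority order decides.
#' @param tie_abs Absolute tie floor (mm) for near-zero RMSEs (degenerate
#'   noiseless cases).
#' @return A list of class `candidate_configs`.
#' @export
candidate_configs <- function(radius = 1 / 3, fcm_par = NULL,
                              anfis_cfg = anfis_config(radius = radius),
                              kinds = c("FCM_FIS", "ANFIS", "SUB_FIS"),
                              tie_rel = 0.01, tie_abs = 1e-6) {
  structure(list(radius = radius, fcm_par = fcm_par, anfis_cfg = anfis_cfg,
                 kinds = kinds, tie_rel = tie_rel, tie_abs = tie_abs),
            class = "candidate_configs")
}

train_candidate <- function(kind, train, configs) {
  switch(kind,
         SUB_FIS = build_sub_fis(train, radius = configs$radius),
         FCM_FIS = build_fcm_fis(train, radius = configs$radius,
                                 fcm_par = configs$fcm_par),
         ANFIS = anfis_train(train, configs$anfis_cfg),
         stop("unknown model kind: ", kind))
}

check_rmse_mm <- function(model, check) {
  pred <- predict(model, check$X)
  rmse(targeting_errors(pred, check$Y))
}

#' Model selectivity: pick the best candidate on a temporal holdout
#'
#' Trains every candidate (SUB-FIS, FCM-FIS, ANFIS) on the earliest 75% of
#' the training set, scores each by 3-D RMSE on the most recent 25%, picks
#' the minimizer (ties, within the configured tolerance, break by the
#' priority order of `configs$kinds`), and finally retrains the winner on
#' the full training set before deployment.
#'
#' @param train A `training_set` with at least 4 points.
#' @param configs A [candidate_configs()].
#' @return List with `model` (the winner retrained on all points) and
#'   `report` (a `selection_report` with per-candidate check RMSE, the chosen
#'   kind, split sizes, and a tie flag).
#' @export
select_model <- function(train, configs = candidate_configs()) {
  parts <- split_training(train)
  rmses <- stats::setNames(rep(NA_real_, length(configs$kinds)), configs$kinds)
  failures <- character(0)
  for (kind in configs$kinds) {
    res <- tryCatch(
      check_rmse_mm(train_candidate(kind, parts$fit, configs), parts$check),
      error = function(e) {
        failures[[kind]] <<- conditionMessage(e)
        NA_real_
      })
    rmses[[kind]] <- res
  }
  if (all(is.na(rmses))) stop("all candidate models failed to train")
  best_rmse <- min(rmses, na.rm = TRUE)
  tied <- !is.na(rmses) &
    (rmses - best_rmse) <= pmax(configs$tie_rel * best_rmse, configs$tie_abs)
  chosen <- configs$kinds[which(tied)[1L]]   # kinds are in priority order
  report <- structure(
    list(check_rmse = rmses, chosen = chosen,
         n_fit = n_points(parts$fit), n_check = n_points(parts$check),
         tie = sum(tied) > 1L, failures = failures),
    class = "selection_report")
  model <- train_candidate(chosen, train, configs)
  list(model = model, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: fit %d / check %d points\n", x$n_fit, x$n_check))
  for (k in names(x$check_rmse)) {
    cat(sprintf("  %-8s check RMSE %s mm%s\n", k,
                formatC(x$check_rmse[[k]], digits = 4, format = "fg"),
                if (identical(k, x$chosen)) "  <- selected" else ""))
  }
  if (x$tie) cat("  (tie within tolerance; priority order applied)\n")
  invisible(x)
}

#' Tracking model state for intra-treatment updating
#'
#' Holds the current correlation model, the accumulated training set (all
#' imaging points gathered so far), the configuration used to (re)build the
#' model, and an update counter.
#'
#' @param model A fitted `correlation_model`.
#' @param train The `training_set` the model was built from.
#' @param configs The [candidate_configs()] used for rebuilds.
#' @return An object of class `model_state`.
#' @export
model_state <- function(model, train, configs = candidate_configs()) {
  stopifnot(inherits(model, "correlation_model"), inherits(train, "training_set"))
  structure(list(model = model, train = train, configs = configs,
                 n_updates = 0L),
            class = "model_state")
}

#' Update the model with new imaging points
#'
#' Intra-treatment updating rebuilds the correlation model from scratch: the
#' new imaging data are appended to all previously gathered data and the same
#' model kind is retrained with the same hyperparameters on the accumulated
#' set.
#'
#' @param state A `model_state`.
#' @param new_points A non-empty `training_set` whose timestamps all follow
#'   the accumulated ones.
#' @return The updated `model_state` (accumulated set grown, model rebuilt,
#'   counter incremented).
#' @export
update_model <- function(state, new_points) {
  stopifnot(inherits(state, "model_state"))
  if (!inherits(new_points, "training_set") || n_points(new_points) < 1L) {
    stop("new_points must be a non-empty training_set")
  }
  t_old <- state$train$timestamps
  if (min(new_points$timestamps) <= max(t_old)) {
    stop("new imaging points must be timestamped after the accumulated data")
  }
  merged <- training_set(rbind(state$train$X, new_points$X),
                         rbind(state$train$Y, new_points$Y),
                         c(t_old, new_points$timestamps))
  state$train <- merged
  state$model <- train_candidate(state$model$model_kind, merged, state$configs)
  state$n_updates <- state$n_updates + 1L
  state
}

#' Track the tumor through an external trace
#'
#' Applies the current correlation model sample-by-sample at the external
#' trace's native timestamps, producing the inferred internal trajectory.
#' Inference is stateless: output length equals input length.
#'
#' @param state A `model_state` (or a bare `correlation_model`).
#' @param external A 9-channel `marker_trace`.
#' @return A 3-channel `marker_trace` of predicted internal positions (mm).
#' @export
track <- function(state, external) {
  model <- if (inherits(state, "model_state")) state$model else state
  stopifnot(inherits(model, "correlation_model"))
  if (!inherits(external, "marker_trace") || n_channels(external) != 9L) {
    stop("external trace must be a 9-channel marker_trace")
  }
  pred <- predict(model, external$values)
  marker_trace(external$timestamps, pred,
               sample_rate_hint = external$sample_rate_hint)
}
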