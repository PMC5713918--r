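#' Subtractive clustering potentials
#'
#' The potential of a data point is the density of neighboring points: a sum
#' of Gaussian kernels of influence range `r` over all points (including the
#' point itself, which contributes exp(0) = 1),
#' \deqn{D_i = \sum_j \exp(-\|x_i - x_j\|^2 / (r/2)^2).}
#'
#' @param points Numeric matrix, N x d, in normalized coordinates.
#' @param r Influence range (fraction of data width per dimension), > 0.
#' @return Numeric vector of length N of potentials, each >= 1.
#' @export
compute_potentials <- function(points, r) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one point")
  if (r <= 0) stop("r must be positive")
  d2 <- pairwise_sq_dists(points, points)
  as.vector(rowSums(exp(-d2 / (r / 2)^2)))
}

# Squared Euclidean distances between rows of A (n x d) and rows of B (m x d).
pairwise_sq_dists <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Parameters of the subtractive clustering procedure
#'
#' @param r Influence range as a fraction of the (normalized) data width per
#'   dimension; the operating point is 1/3 of the training-data-space width.
#' @param squash_factor Ratio of the potential-revision radius to `r` (> 1).
#' @param accept_ratio Relative potential above which a candidate is accepted
#'   outright.
#' @param reject_ratio Relative potential below which candidates are rejected
#'   and the procedure stops.
#' @return A list of class `subtractive_params`.
#' @export
subtractive_params <- function(r = 1 / 3, squash_factor = 1.25,
                               accept_ratio = 0.5, reject_ratio = 0.15) {
  if (r <= 0 || r > 1) stop("r must be in (0, 1]")
  if (squash_factor <= 1) stop("squash_factor must exceed 1")
  if (!(reject_ratio > 0 && reject_ratio < accept_ratio && accept_ratio <= 1)) {
    stop("need 0 < reject_ratio < accept_ratio <= 1")
  }
  structure(list(r = r, squash_factor = squash_factor,
                 accept_ratio = accept_ratio, reject_ratio = reject_ratio),
            class = "subtractive_params")
}

#' Subtractive clustering (Chiu's procedure)
#'
#' Every data point is a candidate cluster center with potential proportional
#' to the density of its neighbors. Centers are selected greedily: the
#' maximum-potential point becomes a center, a squashed Gaussian (radius
#' `squash_factor * r`) is subtracted from all potentials, and selection
#' continues while the relative potential stays above `accept_ratio`. Below
#' `reject_ratio` the procedure stops; in the band between, the standard
#' distance-based criterion (d_min/r + P/P1 >= 1) decides. Ties in potential
#' break to the lowest point index, making the procedure fully deterministic.
#'
#' @param points Numeric matrix, N x d, normalized coordinates.
#' @param params A [subtractive_params()] object.
#' @return A list of class `cluster_result` with `centers` (C x d, a subset of
#'   the data points), `center_index`, and `potentials` (initial potentials).
#' @export
subtractive_cluster <- function(points, params = subtractive_params()) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < 1L) stop("need at least one point")
  pot0 <- compute_potentials(points, params$r)
  pot <- pot0
  rb <- params$squash_factor * params$r
  d2 <- pairwise_sq_dists(points, points)

  first_pot <- NA_real_
  centers_idx <- integer(0)
  repeat {
    k <- which.max(pot)          # which.max returns the first (lowest) index on ties
    pk <- pot[k]
    if (is.na(first_pot)) first_pot <- pk
    rel <- pk / first_pot
    accept <- FALSE
    if (rel > params$accept_ratio) {
      accept <- TRUE
    } else if (rel < params$reject_ratio) {
      break
    } else {
      dmin <- sqrt(min(d2[k, centers_idx]))
      if (dmin / params$r + rel >= 1) {
        accept <- TRUE
      } else {
        pot[k] <- 0              # shelve this candidate, retry with the next
        if (all(pot <= 0)) break
        next
      }
    }
    if (accept) {
      centers_idx <- c(centers_idx, k)
      pot <- pot - pk * exp(-d2[, k] / (rb / 2)^2)
      pot[centers_idx] <- 0
      if (all(pot <= 0)) break
    }
  }
  if (length(centers_idx) == 0L) centers_idx <- which.max(pot0)
  structure(list(centers = points[centers_idx, , drop = FALSE],
                 center_index = centers_idx,
                 potentials = pot0,
                 method = "subtractive"),
            class = "cluster_result")
}

#' Parameters of fuzzy C-means clustering
#'
#' @param n_clusters Number of clusters C (>= 1).
#' @param m Fuzzifier (> 1); 2 is the conventional choice.
#' @param eps Termination criterion on the membership matrix,
#'   max|U(k+1) - U(k)| < eps, in (0, 1).
#' @param max_iterations Iteration cap.
#' @return A list of class `fcm_params`.
#' @export
fcm_params <- function(n_clusters, m = 2, eps = 1e-5, max_iterations = 200L) {
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (!(eps > 0 && eps < 1)) stop("eps must lie in (0, 1)")
  structure(list(n_clusters = as.integer(n_clusters), m = m, eps = eps,
                 max_iterations = as.integer(max_iterations)),
            class = "fcm_params")
}

# Memberships given centers: u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)).
# A point coincident with a center gets membership 1 there, 0 elsewhere
# (split equally if coincident with several).
fcm_memberships <- function(points, centers, m) {
  d2 <- pairwise_sq_dists(points, centers)
  p <- 1 / (m - 1)
  U <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < 1e-30
  coincident <- rowSums(zero) > 0L
  if (any(!coincident)) {
    inv <- d2[!coincident, , drop = FALSE]^(-p)
    U[!coincident, ] <- inv / rowSums(inv)
  }
  if (any(coincident)) {
    Z <- zero[coincident, , drop = FALSE]
    U[coincident, ] <- Z / rowSums(Z)
  }
  U
}

fcm_objective <- function(points, centers, U, m) {
  d2 <- pairwise_sq_dists(points, centers)
  sum(U^m * d2)
}

#' Fuzzy C-means clustering
#'
#' Minimizes the fuzzified within-cluster scatter
#' \deqn{J_m = \sum_{i=1}^N \sum_{j=1}^C u_{ij}^m \|x_i - c_j\|^2}
#' by alternating the membership update
#' \eqn{u_{ij} = 1 / \sum_k (\|x_i-c_j\| / \|x_i-c_k\|)^{2/(m-1)}} and the
#' center update \eqn{c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m}, stopping
#' when \eqn{\max|U^{(k+1)} - U^{(k)}| < \epsilon} or the iteration cap is
#' reached. By default the initial centers come from subtractive clustering,
#' which also fixes C.
#'
#' @param points Numeric matrix, N x d, normalized coordinates.
#' @param params An [fcm_params()] object; if `NULL`, C is taken from
#'   subtractive clustering with default parameters.
#' @param initial_centers Optional C x d matrix; default: subtractive centers.
#' @param sub_params [subtractive_params()] used when seeding from
#'   subtractive clustering.
#' @return A list of class `cluster_result` with `centers`, `memberships`
#'   (N x C, rows summing to 1), `objective_history` (non-increasing), and
#'   `iterations`.
#' @export
fcm <- function(points, params = NULL, initial_centers = NULL,
                sub_params = subtractive_params()) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < 1L) stop("empty input")
  if (is.null(initial_centers)) {
    initial_centers <- subtractive_cluster(points, sub_params)$centers
  }
  initial_centers <- as.matrix(initial_centers)
  if (is.null(params)) params <- fcm_params(nrow(initial_centers))
  C <- params$n_clusters
  if (C > N) stop("n_clusters exceeds the number of points")
  if (nrow(initial_centers) != C) {
    initial_centers <- initial_centers[seq_len(min(C, nrow(initial_centers))), , drop = FALSE]
    if (nrow(initial_centers) < C) stop("initial_centers has fewer rows than n_clusters")
  }

  centers <- initial_centers
  U <- fcm_memberships(points, centers, params$m)
  J <- fcm_objective(points, centers, U, params$m)
  history <- J
  iter <- 0L
  repeat {
    iter <- iter + 1L
    W <- U^params$m
    centers_new <- sweep(crossprod(W, points), 1L, colSums(W), "/")
    U_new <- fcm_memberships(points, centers_new, params$m)
    history <- c(history, fcm_objective(points, centers_new, U_new, params$m))
    du <- max(abs(U_new - U))
    centers <- centers_new
    U <- U_new
    if (du < params$eps || iter >= params$max_iterations) break
  }
  structure(list(centers = centers, memberships = U,
                 objective_history = history, iterations = iter,
                 method = "fcm"),
            class = "cluster_result")
}
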