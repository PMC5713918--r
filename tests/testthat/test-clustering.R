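test_that("potentials match the direct double-loop sum", {
  expect_equal(compute_potentials(matrix(0.3, 1, 2), r = 0.5), 1)
  expect_equal(compute_potentials(matrix(0.3, 2, 2, byrow = TRUE), r = 0.5),
               c(2, 2))
  set.seed(3)
  pts <- matrix(runif(10), 5, 2)
  r <- 0.5
  direct <- sapply(1:5, function(i) {
    sum(sapply(1:5, function(j) {
      exp(-sum((pts[i, ] - pts[j, ])^2) / (r / 2)^2)
    }))
  })
  expect_equal(compute_potentials(pts, r), direct, tolerance = 1e-12)
  expect_true(all(compute_potentials(pts, r) >= 1))
})

test_that("subtractive clustering finds one center per tight blob", {
  # all points identical -> exactly one center
  same <- matrix(0.4, 6, 3)
  res <- subtractive_cluster(same, subtractive_params(r = 0.3))
  expect_equal(nrow(res$centers), 1L)
  expect_equal(res$centers[1, ], rep(0.4, 3))

  # two tight, well-separated blobs -> 2 centers, one in each,
  # agreeing with an independent greedy reference implementation
  set.seed(9)
  blob1 <- matrix(runif(16, 0.0, 0.05), 8, 2)
  blob2 <- matrix(runif(16, 0.9, 0.95), 8, 2)
  pts <- rbind(blob1, blob2)
  p <- subtractive_params(r = 0.3)
  res <- subtractive_cluster(pts, p)
  expect_equal(nrow(res$centers), 2L)
  in1 <- res$centers[, 1] < 0.5
  expect_true(sum(in1) == 1 && sum(!in1) == 1)

  greedy_reference <- function(points, par) {
    d2 <- as.matrix(dist(points))^2
    pot <- sapply(seq_len(nrow(points)), function(i) {
      sum(exp(-d2[i, ] / (par$r / 2)^2))
    })
    p1 <- max(pot)
    centers <- integer(0)
    repeat {
      k <- which.max(pot)
      if (pot[k] > par$accept_ratio * p1) {
        centers <- c(centers, k)
        pot <- pot - pot[k] * exp(-d2[, k] / (par$squash_factor * par$r / 2)^2)
        pot[centers] <- 0
      } else break
      if (all(pot <= 0)) break
    }
    centers
  }
  expect_equal(res$center_index, unname(greedy_reference(pts, p)))
})

test_that("subtractive clustering is deterministic and order-invariant", {
  set.seed(21)
  pts <- matrix(runif(40), 20, 2)
  p <- subtractive_params(r = 0.4)
  a <- subtractive_cluster(pts, p)
  b <- subtractive_cluster(pts, p)
  expect_identical(a$centers, b$centers)
  perm <- sample(20)
  c3 <- subtractive_cluster(pts[perm, ], p)
  # same set of centers regardless of row order (potentials are distinct)
  expect_equal(c3$centers[order(c3$centers[, 1]), ],
               a$centers[order(a$centers[, 1]), ], tolerance = 1e-12)
})

test_that("FCM with one cluster returns the arithmetic centroid", {
  set.seed(2)
  pts <- matrix(runif(30), 10, 3)
  res <- fcm(pts, fcm_params(1), initial_centers = pts[1, , drop = FALSE])
  expect_equal(as.vector(res$centers), colMeans(pts), tolerance = 1e-6)
  expect_true(all(abs(rowSums(res$memberships) - 1) < 1e-9))
})

test_that("FCM separates two blobs and satisfies stationarity", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(20, 0, 0.03), 10, 2),
               matrix(rnorm(20, 1, 0.03), 10, 2))
  res <- fcm(pts, fcm_params(2, m = 2),
             initial_centers = pts[c(1, 11), ])
  dom <- apply(res$memberships, 1, max)
  expect_true(all(dom > 0.9))
  expect_true(all(diff(res$objective_history) <= 1e-12))
  # first-order stationarity of J_m in the centers, checked by perturbation
  J0 <- fuzzytrack:::fcm_objective(pts, res$centers, res$memberships, 2)
  for (k in 1:10) {
    pert <- res$centers + matrix(rnorm(4, 0, 1e-4), 2, 2)
    Jp <- fuzzytrack:::fcm_objective(pts, pert, res$memberships, 2)
    expect_gte(Jp, J0 - 1e-10)
  }
})

test_that("FCM attains the grid-search optimum on a tiny 1-D problem", {
  pts <- matrix(c(0, 0.1, 0.8, 1), 4, 1)
  res <- fcm(pts, fcm_params(2, m = 2, eps = 1e-9, max_iterations = 500),
             initial_centers = matrix(c(0.05, 0.9), 2, 1))
  Jfit <- tail(res$objective_history, 1)
  grid <- seq(0, 1, by = 0.005)
  best <- Inf
  for (c1 in grid) for (c2 in grid) {
    U <- fuzzytrack:::fcm_memberships(pts, matrix(c(c1, c2), 2, 1), 2)
    J <- fuzzytrack:::fcm_objective(pts, matrix(c(c1, c2), 2, 1), U, 2)
    if (J < best) best <- J
  }
  expect_lt(Jfit, best * 1.01 + 1e-12)
})

test_that("FCM memberships stay row-normalized at every iteration", {
  set.seed(8)
  pts <- matrix(runif(24), 12, 2)
  init <- pts[c(2, 9), ]
  for (k in 1:6) {
    res <- fcm(pts, fcm_params(2, eps = 1e-12, max_iterations = k),
               initial_centers = init)
    expect_true(all(abs(rowSums(res$memberships) - 1) < 1e-9))
    expect_true(all(res$memberships >= 0 & res$memberships <= 1))
  }
})

test_that("FCM rejects impossible configurations", {
  expect_error(fcm(matrix(0, 2, 2), fcm_params(3),
                   initial_centers = matrix(0, 3, 2)), "exceeds")
  expect_error(fcm_params(2, m = 1), "fuzzifier")
  expect_error(fcm_params(0), "n_clusters")
})
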