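test_that("Gaussian membership evaluation matches its closed form", {
  mf <- gaussian_mf(0.4, 0.2)
  expect_equal(mf_eval(mf, 0.4), 1)
  expect_equal(mf_eval(mf, 0.4 + 0.2), exp(-0.5))
  expect_equal(mf_eval(mf, 0.4 - 0.2), mf_eval(mf, 0.4 + 0.2))  # symmetry
  x <- seq(-1, 2, length.out = 101)
  expect_equal(mf_eval(mf, x), exp(-(x - 0.4)^2 / (2 * 0.2^2)),
               tolerance = 1e-15)
  # width floor for singleton clusters
  expect_gte(gaussian_mf(0, 0)$sigma, 1e-4)
})

test_that("firing strengths are per-dimension products and normalize to 1", {
  rb <- make_rule_base(R = 3, d = 9, seed = 2)
  set.seed(4)
  x <- runif(9)
  w <- firing_strengths(rb, x)
  direct <- sapply(1:3, function(i) {
    prod(exp(-(x - rb$centers[i, ])^2 / (2 * rb$sigmas[i, ]^2)))
  })
  expect_equal(w, direct, tolerance = 1e-12)
  expect_true(all(w > 0))
  # at a rule's own premise center the strength is exactly 1
  expect_equal(firing_strengths(rb, rb$centers[2, ])[2], 1)

  wb <- normalize_firing(w)
  expect_equal(sum(wb), 1, tolerance = 1e-12)
  expect_equal(normalize_firing(c(0.2, 0.2)), c(0.5, 0.5))
  expect_equal(normalize_firing(5), 1)
  expect_error(normalize_firing(c(0, 0)), "zero")
})

test_that("Sugeno inference aggregates rule outputs correctly", {
  # single rule: output is exactly its affine map, any input
  rb1 <- make_rule_base(R = 1, d = 9, seed = 5)
  set.seed(6)
  for (k in 1:5) {
    x <- runif(9, -2, 2)
    expect_equal(infer(rb1, x), sum(rb1$coef[1, ] * x) + rb1$intercept[1],
                 tolerance = 1e-12)
  }

  # identical consequents: output equals the common map everywhere
  rb2 <- make_rule_base(R = 3, d = 9, seed = 7)
  rb2$coef <- matrix(rep(rb2$coef[1, ], each = 3), 3, 9)
  rb2$intercept <- rep(rb2$intercept[1], 3)
  x <- runif(9)
  expect_equal(infer(rb2, x), sum(rb2$coef[1, ] * x) + rb2$intercept[1],
               tolerance = 1e-12)

  # 3-rule aggregation against a hand-rolled sum-of-terms oracle
  rb3 <- make_rule_base(R = 3, d = 9, seed = 8)
  for (k in 1:50) {
    x <- runif(9)
    w <- sapply(1:3, function(i) {
      prod(exp(-(x - rb3$centers[i, ])^2 / (2 * rb3$sigmas[i, ]^2)))
    })
    f <- sapply(1:3, function(i) sum(rb3$coef[i, ] * x) + rb3$intercept[i])
    expect_equal(infer(rb3, x), sum(w * f) / sum(w), tolerance = 1e-12)
    # convexity bound: inference lies between the extreme rule outputs
    expect_gte(infer(rb3, x), min(f) - 1e-12)
    expect_lte(infer(rb3, x), max(f) + 1e-12)
  }
})

test_that("batch inference agrees with scalar inference", {
  rb <- make_rule_base(R = 4, d = 9, seed = 9)
  set.seed(10)
  X <- matrix(runif(20 * 9), 20, 9)
  batch <- fuzzytrack:::infer_batch(rb, X)
  single <- apply(X, 1, function(x) infer(rb, x))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("consequent estimation recovers exact and OLS solutions", {
  set.seed(11)
  # exactly linear data are reproduced regardless of premise layout
  X <- matrix(runif(30 * 9), 30, 9)
  a <- rnorm(9); b0 <- 0.3
  y <- as.vector(X %*% a) + b0
  rb <- make_rule_base(R = 3, d = 9, seed = 12, fitted = FALSE)
  fit <- fit_consequents(rb, X, y)
  pred <- fuzzytrack:::infer_batch(fit, X)
  expect_lt(max(abs(pred - y)), 1e-8)

  # one rule with n >= 10: identical to ordinary least squares
  rb1 <- make_rule_base(R = 1, d = 9, seed = 13, fitted = FALSE)
  ynoise <- y + rnorm(30, 0, 0.1)
  fit1 <- fit_consequents(rb1, X, ynoise)
  ols <- stats::lm.fit(cbind(X, 1), ynoise)$coefficients
  expect_equal(c(fit1$coef[1, ], fit1$intercept[1]), unname(ols),
               tolerance = 1e-8)
  expect_false(isTRUE(fit1$ls_warning))

  # rank-deficient design: duplicated rows, fewer points than parameters
  Xd <- X[rep(1:3, 3), ]
  yd <- ynoise[rep(1:3, 3)]
  fitd <- fit_consequents(rb, Xd, yd)
  expect_true(all(is.finite(fitd$coef)))
  expect_true(fitd$ls_warning)
})

test_that("builders yield one rule per cluster and exact linear recovery", {
  pat <- make_linear_patient(seed = 3, n_imaging = 27)
  tr <- pat$imaging
  m_sub <- build_sub_fis(tr)
  # rule count equals the subtractive center count of each joint space
  spec <- fit_normalization(tr)
  Xn <- fuzzytrack:::normalize_inputs(spec, tr$X)
  Yn <- fuzzytrack:::normalize_outputs(spec, tr$Y)
  for (k in 1:3) {
    cl <- subtractive_cluster(cbind(Xn, Yn[, k]), subtractive_params(r = 1 / 3))
    expect_equal(fuzzytrack:::n_rules(m_sub$rule_bases[[k]]), nrow(cl$centers))
  }
  # noiseless affine coupling: training and held-out RMSE below 1e-6 mm
  held <- sample_imaging(pat, 15, seed = 99, window = c(5, 295))
  for (m in list(m_sub, build_fcm_fis(tr))) {
    expect_lt(rmse(targeting_errors(predict(m, tr$X), tr$Y)), 1e-6)
    expect_lt(rmse(targeting_errors(predict(m, held$X), held$Y)), 1e-6)
  }
})

test_that("FCM-FIS diagnostics and C=1 behavior are consistent", {
  # C = 1 equals a single global linear regression predictor
  set.seed(14)
  X <- matrix(runif(20 * 9), 20, 9)
  Y <- matrix(rnorm(60), 20, 3)
  tr <- training_set(X, Y, 1:20)
  spec <- fit_normalization(tr)
  Xn <- fuzzytrack:::normalize_inputs(spec, tr$X)
  Yn <- fuzzytrack:::normalize_outputs(spec, tr$Y)
  rb <- rule_base(matrix(colMeans(Xn), 1), matrix(0.3, 1, 9))
  fit <- fit_consequents(rb, Xn, Yn[, 1])
  ols <- stats::lm.fit(cbind(Xn, 1), Yn[, 1])$coefficients
  expect_equal(c(fit$coef[1, ], fit$intercept[1]), unname(ols),
               tolerance = 1e-6)
})

test_that("predictions are invariant to input unit rescaling", {
  pat <- make_linear_patient(seed = 6, n_imaging = 12, noise = 0.2)
  tr <- pat$imaging
  m1 <- build_fcm_fis(tr)
  # scale one raw input channel by 1000: same mm predictions
  scale_vec <- c(1000, rep(1, 8))
  X2 <- sweep(tr$X, 2, scale_vec, "*")
  m2 <- build_fcm_fis(training_set(X2, tr$Y, tr$timestamps))
  probe <- sample_imaging(pat, 10, seed = 55, window = c(10, 290))$X
  expect_equal(predict(m2, sweep(probe, 2, scale_vec, "*")),
               predict(m1, probe), tolerance = 1e-9)
})

test_that("model building is deterministic", {
  pat <- make_linear_patient(seed = 8, n_imaging = 10, noise = 0.3)
  tr <- pat$imaging
  m1 <- build_sub_fis(tr)
  m2 <- build_sub_fis(tr)
  probe <- matrix(runif(90, -30, 230), 10, 9)
  expect_identical(predict(m1, probe), predict(m2, probe))
  f1 <- build_fcm_fis(tr)
  f2 <- build_fcm_fis(tr)
  expect_identical(predict(f1, probe), predict(f2, probe))
})
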