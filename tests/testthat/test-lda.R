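test_that("two separated 1-D groups give one function and perfect recall", {
  set.seed(1)
  X <- matrix(c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)), ncol = 1)
  g <- rep(1:2, each = 10)
  model <- fit_lda(X, g)
  expect_identical(model$m, 1L)
  expect_identical(predict_class(model, X), as.character(g))
})

test_that("m = min(G - 1, p) for 4 and 5 groups on 6 predictors", {
  ref <- generate_reference(n_per_group = 6, seed = 21)
  am <- attribute_transform(ref$table)
  expect_identical(fit_lda(am, ref$groups)$m, 3L)
  g5 <- ref$groups
  g5[tail(which(g5 == 4L), 3)] <- 5L  # split group 4 to make a fifth group
  expect_identical(fit_lda(am, g5)$m, 4L)
})

test_that("projected training data have identity within-group covariance", {
  d <- toy_lda_data(seed = 2, n = 20)
  model <- fit_lda(d$X, d$groups)
  Z <- project(model, d$X)
  W <- matrix(0, model$m, model$m)
  for (g in unique(d$groups)) {
    Zg <- scale(Z[d$groups == g, , drop = FALSE], scale = FALSE)
    W <- W + crossprod(Zg)
  }
  W <- W / (nrow(Z) - length(unique(d$groups)))
  expect_equal(W, diag(model$m), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("projection is the documented centred matrix product", {
  d <- toy_lda_data(seed = 3)
  model <- fit_lda(d$X, d$groups)
  # grand training mean maps to the origin
  expect_equal(as.numeric(project(model, matrix(model$xbar, 1))),
               rep(0, model$m), tolerance = 1e-12)
  # determinism: projecting a group mean twice is bit-identical
  mu <- model$means[2, , drop = FALSE]
  expect_identical(project(model, mu), project(model, mu))
  # hand arithmetic on a 2x2 case
  hand <- structure(list(p = 2L, m = 2L, xbar = c(1, 2),
                         scalings = matrix(c(0.5, 0.2, 0.1, 0.3), 2),
                         means = matrix(0, 2, 2)),
                    class = "lda_model")
  expect_equal(as.numeric(project(hand, matrix(c(3, 4), 1))),
               c(2 * 0.5 + 2 * 0.2, 2 * 0.1 + 2 * 0.3))

  expect_error(project(model, matrix(0, 1, 5)), "predictor columns")
})

test_that("posteriors are normalised and match the full-space Gaussian oracle", {
  d <- toy_lda_data(seed = 4, n = 15)
  model <- fit_lda(d$X, d$groups)
  set.seed(5)
  Xnew <- matrix(rnorm(40, sd = 4), 20, 2)
  post <- posterior(model, Xnew)
  expect_equal(unname(rowSums(post)), rep(1, 20), tolerance = 1e-12)
  expect_equal(unname(post), unname(oracle_gaussian_posterior(model, Xnew)),
               tolerance = 1e-10)
  # a point at a group mean wins under uniform priors
  mu <- fit_lda(d$X, d$groups, priors = "uniform")
  p1 <- posterior(mu, model$means[3, , drop = FALSE])
  expect_identical(unname(which.max(p1)), 3L)

  expect_error(posterior(model, matrix(c(1, NA), 1)), "non-finite")
})

test_that("exact posterior ties break towards the lowest group index", {
  X <- matrix(c(-1, -1.25, -0.75, 1, 1.25, 0.75), ncol = 1)
  g <- rep(c(1, 3), each = 3)  # symmetric about 0
  model <- fit_lda(X, g, priors = "uniform")
  post <- posterior(model, matrix(0, 1, 1))
  expect_equal(unname(post[1, 1]), unname(post[1, 2]), tolerance = 1e-15)
  expect_identical(predict_class(model, matrix(0, 1, 1)), "1")
})

test_that("classification agrees with MASS::lda label-for-label", {
  skip_if_not_installed("MASS")
  for (seed in c(6, 7)) {
    ref <- generate_reference(n_per_group = 10, seed = seed)
    am <- attribute_transform(ref$table)
    arch <- attribute_transform(
      generate_archaeological(n = 25, seed = seed + 100,
                              contamination = 0.3)$table)
    model <- fit_lda(am, ref$groups)
    fit <- MASS::lda(unclass(am), grouping = factor(ref$groups))
    pm <- predict(fit, unclass(arch))
    expect_identical(predict_class(model, arch), as.character(pm$class))
    expect_equal(unname(posterior(model, arch)), unname(pm$posterior),
                 tolerance = 1e-8)
  }
})

test_that("sign flips and shared column shifts change no classification", {
  ref <- generate_reference(n_per_group = 8, seed = 8)
  am <- attribute_transform(ref$table)
  arch <- attribute_transform(generate_archaeological(n = 15, seed = 9)$table)
  model <- fit_lda(am, ref$groups)
  base <- predict_class(model, arch)

  flipped <- model
  flipped$scalings[, 2] <- -flipped$scalings[, 2]
  flipped$centroids <- project(flipped, flipped$means)
  expect_identical(predict_class(flipped, arch), base)
  expect_equal(posterior(flipped, arch), posterior(model, arch),
               tolerance = 1e-12)

  # affine robustness: constant added to one column of train and test alike
  am2 <- unclass(am); am2[, 3] <- am2[, 3] + 5
  arch2 <- unclass(arch); arch2[, 3] <- arch2[, 3] + 5
  model2 <- fit_lda(am2, ref$groups)
  expect_identical(unname(predict_class(model2, arch2)), unname(base))
})

test_that("duplicating the training set preserves classifications", {
  d <- toy_lda_data(seed = 10, n = 25)
  m1 <- fit_lda(d$X, d$groups, priors = "uniform")
  m2 <- fit_lda(rbind(d$X, d$X), c(d$groups, d$groups), priors = "uniform")
  set.seed(11)
  Xnew <- matrix(rnorm(60, sd = 4), 30, 2)
  expect_identical(predict_class(m2, Xnew), predict_class(m1, Xnew))
  # posteriors agree up to the n-G pooled-divisor effect, which shrinks
  # with n; at n = 75 the difference is far below 1%
  expect_equal(posterior(m2, Xnew), posterior(m1, Xnew), tolerance = 1e-2)
})

test_that("singular pooled covariance triggers the named ridge fallback", {
  d <- toy_lda_data(seed = 12)
  X <- cbind(d$X, dead = 0)  # an all-zero attribute column
  expect_warning(expect_warning(
    model <- fit_lda(X, d$groups),
    "all-zero predictor column.*dead"), "ridge")
  post <- suppressWarnings(posterior(model, X))
  expect_true(all(is.finite(post)))
  expect_equal(unname(rowSums(post)), rep(1, nrow(X)), tolerance = 1e-12)
  expect_identical(suppressWarnings(predict_class(model, X)),
                   as.character(d$groups))

  # ridge is inert on well-conditioned data: same result for any eps
  m_small <- fit_lda(d$X, d$groups, ridge_eps = 1e-12)
  m_large <- fit_lda(d$X, d$groups, ridge_eps = 1e-2)
  expect_identical(m_small$scalings, m_large$scalings)
})

test_that("fit_lda validates groups and priors", {
  d <- toy_lda_data()
  expect_error(fit_lda(d$X, rep(1, nrow(d$X))), "two groups")
  expect_error(fit_lda(d$X, c(1, rep(2:3, length.out = nrow(d$X) - 1))),
               ">= 2 members")
  expect_error(fit_lda(d$X, d$groups, priors = c(0.5, 0.5)), "priors")
  pri <- fit_lda(d$X, d$groups, priors = c(0.2, 0.3, 0.5))$priors
  expect_equal(unname(pri), c(0.2, 0.3, 0.5))
})
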