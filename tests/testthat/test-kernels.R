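test_that("kernel values match their defining formulas", {
  ks_g <- kernel_spec("gaussian", sigma_v = 2)
  expect_equal(eval_kernel(ks_g, c(1, 2, 3), c(1, 2, 3)), 1)

  ks_s <- kernel_spec("scalar_product")
  expect_equal(eval_kernel(ks_s, c(1, 0), c(0, 1)), 0)
  expect_equal(eval_kernel(ks_s, c(1, 2), c(3, 4)), 11)

  ## two-block indicator kernel against a direct one-line oracle
  ks_i <- kernel_spec("gaussian_indicator", sigma_v = 1, sigma_r = 0.5)
  x <- c(0.3, -0.2, 0.5, 0.8)   # last entry is the indicator
  y <- c(0.1, 0.4, -0.3, 0.2)
  oracle <- exp(-sum((x[1:3] - y[1:3])^2) / (2 * 1^2) - (x[4] - y[4])^2 / (2 * 0.5^2))
  expect_equal(eval_kernel(ks_i, x, y), oracle, tolerance = 1e-12)

  ## weighted gaussian with bias inside the exponent
  w <- c(2, 0.5, 1)
  ks_w <- kernel_spec("weighted_gaussian", sigma_v = 1.5, weights = w, bias = 0.3)
  a <- c(0.2, -0.1, 0.7); b <- c(-0.4, 0.3, 0.1)
  oracle_w <- exp(-(sum(w * (a - b)^2) + 0.3) / (2 * 1.5^2))
  expect_equal(eval_kernel(ks_w, a, b), oracle_w, tolerance = 1e-12)
})

test_that("kernel spec validates its parameters", {
  expect_error(kernel_spec("gaussian", sigma_v = 0), "positive")
  expect_error(kernel_spec("gaussian_indicator", sigma_r = -1), "positive")
  expect_error(kernel_spec("weighted_gaussian", weights = c(1, -1)), "nonnegative")
  expect_error(eval_kernel(kernel_spec("gaussian"), 1:3, 1:4), "dimension")
})

test_that("kernel_vector agrees with an element-wise loop", {
  X <- random_patterns(6, 3, seed = 11)
  y <- random_patterns(6, 1, seed = 12)[, 1]
  for (fam in c("gaussian", "scalar_product")) {
    ks <- kernel_spec(fam, sigma_v = 1.3)
    kv <- kernel_vector(ks, X, y)
    expect_equal(kv, sapply(1:3, function(i) eval_kernel(ks, X[, i], y)),
                 tolerance = 1e-12)
  }
  ks <- kernel_spec("gaussian")
  expect_equal(kernel_vector(ks, X, X[, 2])[2], 1)
  expect_length(kernel_vector(ks, X[, 1, drop = FALSE], y), 1L)
})

test_that("Gram matrices are symmetric PSD with unit diagonal for gaussians", {
  X <- random_patterns(5, 4, seed = 3)
  ks <- kernel_spec("gaussian", sigma_v = 1)
  G <- gram_matrix(ks, X)
  expect_equal(G, t(G))
  expect_equal(diag(G), rep(1, 4))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  expect_equal(gram_matrix(ks, X[, 1, drop = FALSE]), matrix(1, 1, 1))
  expect_equal(gram_matrix(kernel_spec("scalar_product"), X), crossprod(X),
               tolerance = 1e-12)
})

test_that("strong-Mercer check detects feature-space rank deficiency", {
  X <- random_patterns(4, 3, seed = 5)
  ks <- kernel_spec("gaussian", sigma_v = 1)
  expect_true(check_strong_mercer(ks, X)$ok)
  expect_false(check_strong_mercer(ks, cbind(X, X[, 1]))$ok)

  ## scalar product cannot hold more attractors than input dimensions
  Xbig <- random_patterns(3, 5, seed = 6)
  expect_false(check_strong_mercer(kernel_spec("scalar_product"), Xbig)$ok)
  ## ... but a gaussian kernel can (distinct points give full rank)
  expect_true(check_strong_mercer(kernel_spec("gaussian", sigma_v = 1), Xbig)$ok)
})

test_that("kernels are symmetric and gaussian families are uniform", {
  set.seed(42)
  specs <- list(kernel_spec("gaussian", sigma_v = 0.8),
                kernel_spec("scalar_product"),
                kernel_spec("gaussian_indicator", sigma_v = 1.2, sigma_r = 0.4),
                kernel_spec("weighted_gaussian", sigma_v = 1,
                            weights = runif(6, 0.5, 2)))
  for (ks in specs) {
    for (rep in 1:10) {
      x <- rnorm(6); y <- rnorm(6)
      expect_equal(eval_kernel(ks, x, y), eval_kernel(ks, y, x), tolerance = 1e-12)
      if (is_uniform(ks)) {
        cshift <- rnorm(6)
        expect_equal(eval_kernel(ks, x + cshift, y + cshift),
                     eval_kernel(ks, x, y), tolerance = 1e-10)
      }
    }
    ## sampled Mercer positivity
    P <- matrix(rnorm(6 * 7), 6, 7)
    ev <- eigen(gram_matrix(ks, P), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(abs(ev)))
  }
  expect_false(is_uniform(kernel_spec("scalar_product")))
})

test_that("weight constructors produce usable metrics", {
  X <- random_patterns(10, 30, seed = 9)
  X[3, ] <- X[3, ] * 5            # high-variance component is down-weighted
  w <- weights_inverse_sd(X)
  expect_true(all(w > 0))
  expect_lt(w[3], min(w[-3]))

  cls <- rep(1:3, each = 10)
  X2 <- X; X2[1, ] <- X2[1, ] + 2 * cls   # component 1 separates the classes
  wc <- weights_class_stats(X2, cls)
  expect_gt(wc[1], max(wc[-1]))
})

test_that("kernel specs round-trip through JSON", {
  ks <- kernel_spec("weighted_gaussian", sigma_v = 2.5,
                    weights = c(1, 2, 0.5), bias = 0.1)
  ks2 <- kernel_from_json(kernel_to_json(ks))
  expect_equal(ks2$family, ks$family)
  expect_equal(ks2$sigma_v, ks$sigma_v)
  expect_equal(ks2$weights, ks$weights)
  expect_equal(ks2$bias, ks$bias)

  ks3 <- kernel_from_json(kernel_to_json(kernel_spec("gaussian_indicator",
                                                     sigma_v = 3, sigma_r = 0.7)))
  expect_equal(ks3$sigma_r, 0.7)
})
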