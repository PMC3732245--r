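test_that("every stored pattern is a recall fixed point", {
  ## gaussian, m < n
  M <- gaussian_memory(8, 5, seed = 1)
  for (j in 1:5)
    expect_lt(max(abs(recall_step(M, M$attractors[, j]) - M$attractors[, j])), 1e-6)

  ## single-pattern memory
  M1 <- gaussian_memory(4, 1, seed = 2)
  expect_lt(max(abs(recall_step(M1, M1$attractors[, 1]) - M1$attractors[, 1])), 1e-12)

  ## more attractors than input dimensions (m = 3n), gaussian kernel
  X <- random_patterns(16, 48, seed = 3)
  Mbig <- rekam(X, kernel = kernel_spec("gaussian", sigma_v = 1))
  disp <- sapply(1:48, function(j) max(abs(recall_step(Mbig, X[, j]) - X[, j])))
  expect_lt(max(disp), 1e-6)

  ## indicator and weighted families
  Xi <- rbind(random_patterns(6, 4, seed = 4), c(1, 1, 0, 0))
  Mi <- rekam(Xi, kernel = kernel_spec("gaussian_indicator", sigma_v = 2, sigma_r = 0.5))
  for (j in 1:4)
    expect_lt(max(abs(recall_step(Mi, Xi[, j]) - Xi[, j])), 1e-8)
})

test_that("scalar-product recall map is the pseudoinverse projection", {
  set.seed(7)
  X <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))      # orthonormal columns
  M <- rekam(X, kernel = kernel_spec("scalar_product"), box = c(-2, 2))
  P <- X %*% t(X)                                # X X^+ for orthonormal X
  for (rep in 1:5) {
    y <- rnorm(8, sd = 0.3)                       # stays inside the box
    expect_equal(recall_step(M, y), drop(P %*% y), tolerance = 1e-10)
  }
})

test_that("recall converges to the right attractor under noise", {
  M <- gaussian_memory(8, 5, seed = 10)
  r <- recall(M, M$attractors[, 2])
  expect_true(r$converged)
  expect_lte(r$iterations, 2L)
  expect_identical(r$winner, 2L)

  ## well-separated attractors: bandwidth at half the median distance
  ## so each pattern keeps a crisp basin
  Mn <- gaussian_memory(8, 5, seed = 10,
                        sigma_v = 0.5 * median_bandwidth(M$attractors))
  set.seed(77)
  sdev <- 0.1 * sd(as.vector(Mn$attractors))
  hits <- 0L
  for (trial in 1:200) {
    j <- sample.int(5, 1)
    r <- recall(Mn, Mn$attractors[, j] + rnorm(8, sd = sdev), max_iter = 300)
    hits <- hits + (r$converged && r$winner == j)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("batched recall matches one-at-a-time recall", {
  M <- gaussian_memory(6, 4, seed = 21)
  set.seed(22)
  Y0 <- M$attractors[, c(1, 3, 4)] + matrix(rnorm(18, sd = 0.05), 6)
  rb <- recall_batch(M, Y0)
  for (k in 1:3) {
    r1 <- recall(M, Y0[, k])
    expect_equal(rb$patterns[, k], r1$pattern, tolerance = 1e-10)
    expect_identical(rb$winner[k], r1$winner)
  }
})

test_that("nearest_attractor maximizes the response with low-index ties", {
  M <- gaussian_memory(6, 5, seed = 30)
  expect_identical(nearest_attractor(M, M$attractors[, 4]), 4L)
  set.seed(31)
  for (rep in 1:10) {
    y <- rnorm(6)
    loop <- which.max(sapply(1:5, function(i)
      eval_kernel(M$kernel, M$attractors[, i], y)))
    expect_identical(nearest_attractor(M, y), loop)
  }
  ## exact tie: duplicate responses -> smallest index
  Xd <- cbind(c(1, 0), c(-1, 0))
  Md <- rekam(Xd, kernel = kernel_spec("gaussian", sigma_v = 1))
  expect_identical(nearest_attractor(Md, c(0, 0)), 1L)
})

test_that("attraction-radius scaling moves basin boundaries proportionally", {
  X <- cbind(rep(-0.5, 6), rep(0.5, 6))
  M <- rekam(X, kernel = kernel_spec("gaussian", sigma_v = 1))

  boundary <- function(M) {
    lo <- 0; hi <- 1     # fraction along the segment from attractor 1 to 2
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      y <- (1 - mid) * X[, 1] + mid * X[, 2]
      if (nearest_attractor(M, y) == 1L) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(boundary(M), 0.5, tolerance = 1e-3)
  ## scaling identity: lambda = 1 changes nothing
  expect_equal(boundary(set_scale(M, 1, 1)), 0.5, tolerance = 1e-3)
  ## doubling attractor 1's radius pushes the boundary toward attractor 2
  ## (kernel argument scaling: boundary at d1/lambda1 = d2 => 2/3)
  expect_equal(boundary(set_scale(M, 1, 2)), 2 / 3, tolerance = 1e-3)

  Msp <- rekam(diag(2), kernel = kernel_spec("scalar_product"))
  expect_error(set_scale(Msp, 1, 2), "uniform")
  expect_error(set_scale(M, 1, 0), "positive")
})

test_that("retrieval probability is monotone in the radius scale", {
  set.seed(55)
  X <- gen_smooth_images(10, 64, smooth = 1)
  M <- rekam(X)
  lo <- apply(X, 1, min); hi <- apply(X, 1, max)
  Q <- matrix(runif(64 * 400, lo, hi), 64)       # common random numbers
  freq <- sapply(c(0.8, 0.9, 1, 1.1, 1.25), function(lam) {
    Ms <- set_scale(M, 3, lam)
    mean(apply(rekam:::.rekam_response(Ms, Q), 2, which.max) == 3)
  })
  expect_true(all(diff(freq) >= 0))
})

test_that("attractor edits keep the Gram matrix and factorization exact", {
  M <- gaussian_memory(7, 5, seed = 40)
  G0 <- M$gram

  expect_equal(replace_attractor(M, 2, M$attractors[, 2])$gram, G0, tolerance = 1e-12)

  set.seed(41)
  s <- runif(7, -1, 1)
  M2 <- remove_attractor(add_attractor(M, s), 6L)
  expect_lt(max(abs(M2$gram - G0)), 1e-10)

  ## six random edits: incremental Gram vs full recomputation
  set.seed(42)
  Me <- M
  for (k in 1:6) Me <- replace_attractor(Me, sample.int(5, 1), runif(7, -1, 1))
  expect_lt(max(abs(Me$gram - gram_matrix(Me$kernel, Me$attractors))), 1e-8)

  ## an edit that breaks feature-space independence is refused
  expect_error(replace_attractor(M, 1, M$attractors[, 2]), "independen")
  expect_error(add_attractor(M, M$attractors[, 3]), "independen")
})

test_that("recall iterates stay inside the activation box", {
  M <- gaussian_memory(6, 4, seed = 50)
  set.seed(51)
  for (rep in 1:10) {
    y <- runif(6, -5, 5)
    r <- recall(M, y, max_iter = 30, trajectory = TRUE)
    states <- do.call(cbind, r$trajectory[-1])   # all post-activation iterates
    expect_true(all(states >= M$box[1] - 1e-12 & states <= M$box[2] + 1e-12))
  }
})

test_that("loading refuses rank-deficient pattern sets with a condition report", {
  X <- random_patterns(5, 3, seed = 60)
  expect_error(rekam(cbind(X, X[, 1])), "strong-Mercer")
  expect_error(rekam(random_patterns(3, 5, seed = 61),
                     kernel = kernel_spec("scalar_product")), "strong-Mercer")
})

test_that("model object methods behave", {
  M <- gaussian_memory(9, 4, seed = 70, labels = letters[1:4])
  expect_identical(coef(M), M$attractors)
  expect_output(print(M), "Kernel associative memory")
  sm <- summary(M)
  expect_true(sm$mercer$ok)
  expect_output(print(sm), "strong-Mercer check: passed")

  set.seed(71)
  newdata <- M$attractors + matrix(rnorm(36, sd = 0.02), 9)
  expect_identical(predict(M, newdata), 1:4)
  expect_identical(predict(M, newdata, type = "label"), letters[1:4])
  pat <- predict(M, newdata, type = "pattern")
  expect_equal(dim(pat), c(9L, 4L))

  sim <- simulate(M, nsim = 3, seed = 72, noise_frac = 0.05)
  expect_equal(nrow(sim), 12L)
  expect_true(all(sim$correct))
})
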