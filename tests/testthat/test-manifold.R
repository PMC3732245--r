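sp <- kernel_spec("scalar_product")

test_that("kernel-form distance equals the explicit projector distance", {
  ## identical memories
  M <- gaussian_memory(6, 3, seed = 1)
  expect_equal(memory_distance(M, M), 0, tolerance = 1e-7)

  ## orthogonal lines in the plane: ||diag(1,0) - diag(0,1)||_F = sqrt(2)
  M1 <- rekam(matrix(c(1, 0), 2, 1), kernel = sp, box = c(-2, 2))
  M2 <- rekam(matrix(c(0, 1), 2, 1), kernel = sp, box = c(-2, 2))
  expect_equal(memory_distance(M1, M2), sqrt(2), tolerance = 1e-10)

  ## random subspaces, m = 3, n = 8, against X X^+ projectors
  set.seed(2)
  for (trial in 1:20) {
    A <- matrix(rnorm(24), 8, 3); B <- matrix(rnorm(24), 8, 3)
    MA <- rekam(A, kernel = sp, box = range(A, B))
    MB <- rekam(B, kernel = sp, box = range(A, B))
    PA <- A %*% solve(crossprod(A), t(A))
    PB <- B %*% solve(crossprod(B), t(B))
    expect_equal(memory_distance(MA, MB), norm(PA - PB, "F"), tolerance = 1e-8)
  }
})

test_that("memory distance satisfies the metric axioms", {
  set.seed(3)
  mk <- function(X, ks) rekam(X, kernel = ks, box = c(-6, 6))
  for (ks in list(sp, kernel_spec("gaussian", sigma_v = 2))) {
    for (trial in 1:5) {
      Xs <- lapply(1:3, function(i) matrix(rnorm(12), 6, 2))
      Ms <- lapply(Xs, mk, ks = ks)
      d12 <- memory_distance(Ms[[1]], Ms[[2]])
      d13 <- memory_distance(Ms[[1]], Ms[[3]])
      d23 <- memory_distance(Ms[[2]], Ms[[3]])
      expect_gte(d12, 0)
      expect_equal(d12, memory_distance(Ms[[2]], Ms[[1]]), tolerance = 1e-10)
      expect_lte(d13, d12 + d23 + 1e-10)                       # triangle
      expect_lte(d12, sqrt(2 * 2) + 1e-10)                     # rank bound
      ## same spanned feature subspace (permuted attractors) -> distance 0
      Mp <- mk(Xs[[1]][, 2:1], ks)
      expect_lt(memory_distance(Ms[[1]], Mp), 1e-6)
    }
  }
})

test_that("geodesic endpoints and degenerate cases are exact", {
  M1 <- gaussian_memory(5, 3, seed = 4)
  M2 <- gaussian_memory(5, 3, seed = 5, sigma_v = M1$kernel$sigma_v)
  s0 <- geodesic_point(M1, M2, 0)
  s1 <- geodesic_point(M1, M2, 1)
  expect_lt(memory_distance(s0$point, M1), 1e-6)
  expect_lt(memory_distance(s1$point, M2), 1e-6)
  sd <- geodesic_point(M1, M1, 0.37)
  expect_identical(sd$point$attractors, M1$attractors)
})

test_that("the geodesic reproduces the closed-form rotating line on G(1,2)", {
  th1 <- 0.3; th2 <- 1.1
  M1 <- line_memory(th1); M2 <- line_memory(th2)
  for (t0 in c(0.25, 0.5, 0.8)) {
    sol <- geodesic_point(M1, M2, t0)
    z <- sol$point$attractors[, 1]; z <- z / sqrt(sum(z^2))
    thg <- (1 - t0) * th1 + t0 * th2
    w <- c(cos(thg), sin(thg))
    expect_lt(max(abs(z %*% t(z) - w %*% t(w))), 1e-4)
  }
})

test_that("the interpolation fraction splits the distance as t : (1 - t)", {
  M1 <- line_memory(0.2); M2 <- line_memory(0.8)
  for (t0 in c(0.3, 0.5, 0.7)) {
    sol <- geodesic_point(M1, M2, t0)
    ds <- distance_split(sol)
    expect_equal(unname(ds[1] / sum(ds)), t0, tolerance = 0.02)
    expect_equal(unname(ds[1]), memory_distance(M1, sol$point), tolerance = 1e-8)
    expect_equal(unname(ds[2]), memory_distance(sol$point, M2), tolerance = 1e-8)
    ## the two legs cannot undershoot the direct distance
    expect_gte(sum(ds), memory_distance(M1, M2) - 1e-8)
  }
})

test_that("no perturbed probe beats the geodesic point's distance sum", {
  M1 <- gaussian_memory(5, 3, seed = 6)
  M2 <- rekam(M1$attractors + 0.3 * random_patterns(5, 3, seed = 7),
              kernel = M1$kernel, box = c(-2, 2))
  sol <- geodesic_point(M1, M2, 0.5)
  gsum <- function(M) memory_distance(M1, M, method = "intrinsic") +
    memory_distance(M, M2, method = "intrinsic")
  base <- gsum(sol$point)
  set.seed(8)
  for (probe in 1:10) {
    W <- rekam(sol$point$attractors + matrix(rnorm(15, sd = 0.05), 5, 3),
               kernel = M1$kernel, box = c(-3, 3))
    expect_gte(gsum(W), base - 1e-6)
  }
})

test_that("the analytic objective gradient matches finite differences", {
  spec <- kernel_spec("gaussian", sigma_v = 1.5)
  X <- random_patterns(5, 3, seed = 9)
  M <- rekam(X, kernel = spec)
  Z <- X + 0.2 * random_patterns(5, 3, seed = 10)
  g <- rekam:::.dist2_intrinsic_grad(spec, Z, M)
  num <- matrix(0, 5, 3)
  h <- 1e-6
  for (i in 1:5) for (j in 1:3) {
    e <- matrix(0, 5, 3); e[i, j] <- h
    num[i, j] <- (rekam:::.dist2_intrinsic_grad(spec, Z + e, M, want_grad = FALSE)$value -
                  rekam:::.dist2_intrinsic_grad(spec, Z - e, M, want_grad = FALSE)$value) / (2 * h)
  }
  expect_lt(max(abs(g$grad - num)), 1e-5 * max(1, max(abs(num))))
})

test_that("geometry checks refuse mismatched memories", {
  M1 <- gaussian_memory(5, 3, seed = 11)
  M2 <- gaussian_memory(5, 4, seed = 12)
  expect_error(memory_distance(M1, M2), "different numbers")
  M3 <- rekam(M1$attractors, kernel = kernel_spec("gaussian", sigma_v = 9))
  expect_error(memory_distance(M1, M3), "different kernels")
})
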