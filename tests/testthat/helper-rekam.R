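## Small fixtures built in code; all seeded.

random_patterns <- function(n, m, seed = 1, lim = 1) {
  set.seed(seed)
  matrix(stats::runif(n * m, -lim, lim), n, m)
}

gaussian_memory <- function(n = 8, m = 5, seed = 1, sigma_v = NULL, ...) {
  X <- random_patterns(n, m, seed)
  ks <- kernel_spec("gaussian",
                    sigma_v = if (is.null(sigma_v)) median_bandwidth(X) else sigma_v)
  rekam(X, kernel = ks, ...)
}

## unit-norm column memory on the scalar-product kernel (Grassmann case)
line_memory <- function(theta) {
  rekam(matrix(c(cos(theta), sin(theta)), 2, 1),
        kernel = kernel_spec("scalar_product"), box = c(-2, 2))
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
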