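#' Kernel specification for a kernel associative memory
#'
#' Constructs the kernel family used to embed patterns into feature space.
#' Four families are supported:
#' \describe{
#'   \item{`scalar_product`}{\eqn{\kappa(x,y) = x^\top y}; the classical
#'     pseudoinverse (projection-rule) Hopfield memory arises from this
#'     kernel.  Not uniform, so attraction radii cannot be scaled.}
#'   \item{`gaussian`}{\eqn{\kappa(x,y) = \exp(-\|x-y\|^2 / 2\sigma_v^2)}.}
#'   \item{`gaussian_indicator`}{a two-block Gaussian for patterns whose
#'     last component is a list-membership indicator \eqn{r \in [0,1]}:
#'     \eqn{\exp(-\|\Delta v\|^2/2\sigma_v^2 - \Delta r^2/2\sigma_r^2)},
#'     with separate bandwidths balancing the data block against the
#'     indicator channel.}
#'   \item{`weighted_gaussian`}{\eqn{\exp(-((x-y)^\top \mathrm{diag}(w)
#'     (x-y) + b) / 2\sigma_v^2)}: a Gaussian under a diagonal weighting
#'     metric with optional bias \eqn{b} inside the exponent.  See
#'     [weights_inverse_sd()] and [weights_class_stats()] for the two
#'     weight constructors.}
#' }
#'
#' All Gaussian families are \emph{uniform}: they depend on their
#' arguments only through the difference \eqn{x - y}.  Uniformity is the
#' precondition for attraction-radius scaling (see [set_scale()]).
#'
#' @param family one of `"gaussian"`, `"scalar_product"`,
#'   `"gaussian_indicator"`, `"weighted_gaussian"`.
#' @param sigma_v data-block bandwidth \eqn{\sigma_v > 0}.  Ignored by
#'   `scalar_product`.
#' @param sigma_r indicator-channel bandwidth \eqn{\sigma_r > 0}
#'   (`gaussian_indicator` only).  Default 0.25, a sensible scale for an
#'   indicator confined to \eqn{[0,1]}.
#' @param weights nonnegative weight vector, length = pattern dimension
#'   (`weighted_gaussian` only).
#' @param bias constant offset \eqn{b} added inside the exponent's
#'   quadratic form (`weighted_gaussian` only).  Must be \eqn{\ge 0} so
#'   kernel values stay in \eqn{(0, 1]}.
#' @return an object of class `"kernel_spec"`.
#' @seealso [eval_kernel()], [gram_matrix()], [check_strong_mercer()]
#' @examples
#' ks <- kernel_spec("gaussian", sigma_v = 2)
#' eval_kernel(ks, c(1, 0), c(1, 0))   # 1: Gaussian kernels peak at 0 difference
#' @export
kernel_spec <- function(family = c("gaussian", "scalar_product",
                                   "gaussian_indicator", "weighted_gaussian"),
                        sigma_v = 1, sigma_r = 0.25,
                        weights = NULL, bias = 0) {
  family <- match.arg(family)
  if (family != "scalar_product") {
    if (!is.numeric(sigma_v) || length(sigma_v) != 1L || sigma_v <= 0)
      stop("'sigma_v' must be a single positive number")
  }
  if (family == "gaussian_indicator") {
    if (!is.numeric(sigma_r) || length(sigma_r) != 1L || sigma_r <= 0)
      stop("'sigma_r' must be a single positive number")
  }
  if (family == "weighted_gaussian") {
    if (!is.null(weights)) {
      if (any(!is.finite(weights)) || any(weights < 0))
        stop("'weights' must be finite and nonnegative")
    }
    if (bias < 0) stop("'bias' must be nonnegative")
  }
  structure(list(family = family,
                 sigma_v = sigma_v,
                 sigma_r = if (family == "gaussian_indicator") sigma_r else NULL,
                 weights = if (family == "weighted_gaussian") weights else NULL,
                 bias    = if (family == "weighted_gaussian") bias else 0),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Kernel spec:", x$family)
  if (x$family != "scalar_product") cat("  sigma_v =", format(x$sigma_v))
  if (!is.null(x$sigma_r)) cat("  sigma_r =", format(x$sigma_r))
  if (!is.null(x$weights))
    cat("  weights = <", length(x$weights), " components>", sep = "")
  if (x$bias != 0) cat("  bias =", format(x$bias))
  cat("  uniform =", is_uniform(x), "\n")
  invisible(x)
}

#' Is a kernel uniform (difference-only)?
#'
#' A kernel is uniform when it depends on its arguments only through
#' their difference.  Uniform kernels admit attraction-radius scaling:
#' the response to attractor \eqn{i} can be computed at the shrunken or
#' dilated difference \eqn{(x_i - y)/\lambda_i}.
#'
#' @param spec a [kernel_spec()].
#' @return `TRUE` for all Gaussian families, `FALSE` for `scalar_product`.
#' @export
is_uniform <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  spec$family != "scalar_product"
}

## Quadratic-form coefficients a_k and offset b such that for every
## Gaussian family  kappa(x, y) = exp(-sum_k a_k (x_k - y_k)^2 - b).
.kernel_coefs <- function(spec, n) {
  switch(spec$family,
    gaussian = list(a = rep(1 / (2 * spec$sigma_v^2), n), b = 0),
    gaussian_indicator = {
      if (n < 2L) stop("gaussian_indicator needs dimension >= 2")
      a <- rep(1 / (2 * spec$sigma_v^2), n)
      a[n] <- 1 / (2 * spec$sigma_r^2)
      list(a = a, b = 0)
    },
    weighted_gaussian = {
      w <- spec$weights
      if (is.null(w)) w <- rep(1, n)
      if (length(w) != n)
        stop("length of kernel weights (", length(w),
             ") does not match pattern dimension (", n, ")")
      list(a = w / (2 * spec$sigma_v^2), b = spec$bias / (2 * spec$sigma_v^2))
    },
    stop("not a Gaussian-family kernel"))
}

.as_pattern_matrix <- function(X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X)) stop("patterns must form a numeric matrix")
  if (ncol(X) == 0L) stop("empty pattern matrix")
  X
}

## Weighted squared distances between columns of X (n x mx) and Y (n x my):
## D[i, j] = sum_k a_k (X[k,i] - Y[k,j])^2.  Clipped at 0 against roundoff.
.wsqdist <- function(X, Y, a) {
  sx <- colSums(X * X * a)
  sy <- colSums(Y * Y * a)
  D <- outer(sx, sy, "+") - 2 * crossprod(X * a, Y)
  D[D < 0] <- 0
  D
}

## Cross-kernel matrix K[i, j] = kappa(X[, i], Y[, j]).
.cross_kernel <- function(spec, X, Y) {
  X <- .as_pattern_matrix(X); Y <- .as_pattern_matrix(Y)
  if (nrow(X) != nrow(Y)) stop("pattern dimension mismatch")
  if (spec$family == "scalar_product") return(crossprod(X, Y))
  cf <- .kernel_coefs(spec, nrow(X))
  exp(-.wsqdist(X, Y, cf$a) - cf$b)
}

#' Evaluate a kernel on a pair of patterns
#'
#' @param spec a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return the scalar \eqn{\kappa(x, y)}; symmetric in its arguments, and
#'   in \eqn{(0, 1]} for the Gaussian families (with zero bias).
#' @export
eval_kernel <- function(spec, x, y) {
  if (length(x) != length(y)) stop("pattern dimension mismatch")
  drop(.cross_kernel(spec, matrix(x, ncol = 1L), matrix(y, ncol = 1L)))
}

#' Kernel responses of a pattern set to a probe
#'
#' Entry \eqn{i} is \eqn{\kappa(x_i, y)} for column \eqn{x_i} of `X`.
#'
#' @param spec a [kernel_spec()].
#' @param X pattern matrix, one pattern per column.
#' @param y probe vector.
#' @export
kernel_vector <- function(spec, X, y) {
  drop(.cross_kernel(spec, X, matrix(y, ncol = 1L)))
}

#' Gram matrix of a pattern set
#'
#' The matrix of pairwise kernel values of the stored patterns — the
#' feature-space scalar products.  Its inverse implements pseudoinverse
#' (projective) memory loading.
#'
#' @inheritParams kernel_vector
#' @return symmetric \eqn{m \times m} matrix; unit diagonal for Gaussian
#'   families (zero bias); positive semidefinite.
#' @export
gram_matrix <- function(spec, X) {
  G <- .cross_kernel(spec, X, X)
  (G + t(G)) / 2
}

#' Strong-Mercer (feature-space independence) check
#'
#' A kernel memory requires the stored patterns to be linearly
#' independent in feature space, i.e. an invertible Gram matrix.  Some
#' Mercer kernels (notably the scalar product with more patterns than
#' input dimensions) cannot provide this.  The check passes when the
#' smallest Gram eigenvalue exceeds `tol` times the largest.
#'
#' @inheritParams kernel_vector
#' @param tol relative eigenvalue tolerance; default `1e-10`, the
#'   practical double-precision rank threshold.
#' @return a list with elements `ok` (logical), `min_eigenvalue`,
#'   `max_eigenvalue`, `ratio`, `tol` and `m`.
#' @export
check_strong_mercer <- function(spec, X, tol = 1e-10) {
  G <- gram_matrix(spec, X)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev); mn <- min(ev)
  list(ok = is.finite(mn) && mn > tol * mx,
       min_eigenvalue = mn, max_eigenvalue = mx,
       ratio = mn / mx, tol = tol, m = ncol(G))
}

#' Inverse-spread weights for the weighted Gaussian kernel
#'
#' The default weight rule: one over the per-component standard
#' deviation of the training set, so that high-variance components do
#' not dominate the metric.  Components with (near-)zero spread get the
#' weight of the median component instead of blowing up.
#'
#' @param X training patterns, one per column.
#' @param floor_frac spread below `floor_frac * median spread` is clamped.
#' @return nonnegative weight vector of length `nrow(X)`.
#' @export
weights_inverse_sd <- function(X, floor_frac = 1e-3) {
  X <- .as_pattern_matrix(X)
  s <- apply(X, 1L, stats::sd)
  med <- stats::median(s[s > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  1 / pmax(s, floor_frac * med)
}

#' Class-statistics weights for the weighted Gaussian kernel
#'
#' Alternative weight rule built from per-class first and second
#' moments: the between-class variance of the class means divided by the
#' mean within-class variance (a Fisher-ratio style component score).
#' The inverse-spread rule ([weights_inverse_sd()]) is the default in the
#' experiments since it performs better on the tracking task.
#'
#' @param X training patterns, one per column.
#' @param classes class label per column.
#' @param eps variance floor.
#' @export
weights_class_stats <- function(X, classes, eps = 1e-8) {
  X <- .as_pattern_matrix(X)
  classes <- as.factor(classes)
  if (length(classes) != ncol(X)) stop("one class label per pattern required")
  mu <- sapply(levels(classes), function(cl) rowMeans(X[, classes == cl, drop = FALSE]))
  v  <- sapply(levels(classes), function(cl) {
    Xc <- X[, classes == cl, drop = FALSE]
    if (ncol(Xc) < 2L) rep(0, nrow(X)) else apply(Xc, 1L, stats::var)
  })
  between <- apply(matrix(mu, nrow = nrow(X)), 1L, stats::var)
  within  <- rowMeans(matrix(v, nrow = nrow(X)))
  between / (within + eps)
}

#' Serialize / deserialize a kernel spec as JSON
#'
#' @param spec a [kernel_spec()].
#' @return `kernel_to_json()`: a JSON string; `kernel_from_json()`: a
#'   [kernel_spec()].
#' @export
kernel_to_json <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  jsonlite::toJSON(spec[!vapply(spec, is.null, logical(1L))],
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname kernel_to_json
#' @param json a JSON string produced by `kernel_to_json()`.
#' @export
kernel_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  kernel_spec(family = x$family,
              sigma_v = if (is.null(x$sigma_v)) 1 else x$sigma_v,
              sigma_r = if (is.null(x$sigma_r)) 0.25 else x$sigma_r,
              weights = x$weights,
              bias    = if (is.null(x$bias)) 0 else x$bias)
}

#' Median pairwise distance bandwidth heuristic
#'
#' Default data bandwidth: the median Euclidean distance between
#' distinct training patterns, a standard scale choice for Gaussian
#' kernels.
#'
#' @param X patterns, one per column.
#' @export
median_bandwidth <- function(X) {
  X <- .as_pattern_matrix(X)
  D <- sqrt(.wsqdist(X, X, rep(1, nrow(X))))
  d <- D[upper.tri(D)]
  d <- d[d > 0]
  if (!length(d)) return(1)
  stats::median(d)
}

## Gradient contraction used by the manifold optimizer:
## column i of the result is  sum_j W[i, j] * d kappa(z_i, x_j) / d z_i .
## K may be supplied to avoid recomputing .cross_kernel(spec, Z, X).
.kernel_grad_contract <- function(spec, Z, X, W, K = NULL) {
  Z <- .as_pattern_matrix(Z); X <- .as_pattern_matrix(X)
  if (spec$family == "scalar_product") return(X %*% t(W))
  if (is.null(K)) K <- .cross_kernel(spec, Z, X)
  cf <- .kernel_coefs(spec, nrow(Z))
  M <- W * K
  out <- sweep(Z, 2L, rowSums(M), "*") - X %*% t(M)
  -2 * cf$a * out
}
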