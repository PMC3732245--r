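#' Load a kernel associative memory
#'
#' `rekam()` is the model constructor: it loads a set of patterns
#' (columns of `X`) as attractors of a kernel associative memory.
#' Loading is projective: the synaptic operator in feature space is the
#' orthogonal projector onto the span of the stored patterns' feature
#' images, represented implicitly through the Gram matrix
#' \eqn{G_{ij} = \kappa(x_i, x_j)} and accessed only through kernel
#' evaluations.  One recall step maps a probe \eqn{y} to
#' \deqn{y' = \sigma\!\big(X\, G^{-1} h(y)\big), \qquad
#'       h_i(y) = \kappa\!\big((x_i - y)/\lambda_i\big),}
#' where \eqn{\sigma} is a sigmoid-like (bounded, monotone) activation
#' applied coordinate-wise and \eqn{\lambda_i > 0} are per-attractor
#' attraction-radius scales (all 1 by default; see [set_scale()]).
#' Every stored pattern is a fixed point of this map, and — unlike a
#' Hopfield network — the number of attractors is not limited by the
#' input dimension as long as the kernel keeps their feature images
#' linearly independent (the strong-Mercer condition, checked at load).
#'
#' @param X numeric matrix of patterns to store, one attractor per
#'   column (dimension \eqn{n \times m}).
#' @param kernel a [kernel_spec()]; default is a Gaussian kernel with
#'   the median-pairwise-distance bandwidth of `X`.
#' @param scales positive attraction-radius scale per attractor,
#'   recycled to length \eqn{m}.  Values other than 1 require a uniform
#'   kernel.
#' @param labels optional per-attractor identifiers (e.g. class labels).
#' @param list_tags optional per-attractor list membership used by the
#'   list-learning experiment.
#' @param activation `"clip"` (default): piecewise-linear clip to the
#'   output box, the identity inside it, so stored real-valued patterns
#'   are exact fixed points; or `"tanh"`.
#' @param box length-2 output range of the activation.  Default:
#'   \eqn{[-1, 1]} when all patterns lie inside it, otherwise the
#'   pattern range (so attractors are never clipped).
#' @param scale_mode how attraction-radius scales enter the response:
#'   `"argument"` (default) evaluates the kernel at the shrunken
#'   difference \eqn{(x_i - y)/\lambda_i}, which makes the basin radius
#'   proportional to \eqn{\lambda_i}; `"response"` divides the raw
#'   response \eqn{h_i} by \eqn{\lambda_i} (kept for comparison).
#' @param mercer_tol relative eigenvalue tolerance of the load-time
#'   strong-Mercer check.
#' @param max_condition Gram condition number beyond which a stabilizing
#'   ridge `1e-10 * trace/m` is added (with a warning).
#' @return an object of class `"rekam"`: a list with components
#'   `attractors`, `kernel`, `gram`, `gram_factor` (Cholesky), `scales`,
#'   `labels`, `list_tags`, `activation`, `box`, `n`, `m`.
#' @seealso [recall()], [reconsolidate()], [memory_distance()],
#'   [set_scale()], [predict.rekam()]
#' @examples
#' set.seed(1)
#' X <- matrix(runif(8 * 5, -1, 1), 8, 5)
#' M <- rekam(X)
#' r <- recall(M, X[, 3] + rnorm(8, sd = 0.05))
#' r$winner   # 3
#' @export
rekam <- function(X, kernel = NULL, scales = 1,
                  labels = NULL, list_tags = NULL,
                  activation = c("clip", "tanh"), box = NULL,
                  scale_mode = c("argument", "response"),
                  mercer_tol = 1e-10, max_condition = 1e12) {
  X <- .as_pattern_matrix(X)
  activation <- match.arg(activation)
  scale_mode <- match.arg(scale_mode)
  if (is.null(kernel)) kernel <- kernel_spec("gaussian", sigma_v = median_bandwidth(X))
  stopifnot(inherits(kernel, "kernel_spec"))
  n <- nrow(X); m <- ncol(X)
  scales <- rep_len(as.numeric(scales), m)
  if (any(scales <= 0)) stop("attraction-radius scales must be positive")
  if (any(scales != 1) && !is_uniform(kernel))
    stop("attraction-radius scaling requires a uniform kernel")
  if (!is.null(labels) && length(labels) != m) stop("one label per attractor required")
  if (!is.null(list_tags) && length(list_tags) != m) stop("one list tag per attractor required")
  if (is.null(box)) box <- if (all(abs(X) <= 1)) c(-1, 1) else range(X)
  if (activation == "clip" && (any(X < box[1]) || any(X > box[2])))
    stop("output box must contain all stored patterns")

  M <- structure(list(attractors = X, kernel = kernel, gram = NULL,
                      gram_factor = NULL, scales = scales,
                      labels = labels, list_tags = list_tags,
                      activation = activation, box = as.numeric(box),
                      scale_mode = scale_mode,
                      mercer_tol = mercer_tol, max_condition = max_condition,
                      ridge = 0, edits = 0L, n = n, m = m),
                 class = "rekam")
  .rebuild_gram(M, full = TRUE)
}

## Recompute (full = TRUE) or accept the stored Gram, run the
## strong-Mercer check, apply the conditioning ridge if needed, and
## refresh the Cholesky factor.  All loading/editing paths end here.
.rebuild_gram <- function(M, full = FALSE) {
  if (full || is.null(M$gram)) M$gram <- gram_matrix(M$kernel, M$attractors)
  ev <- eigen(M$gram, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev); mn <- min(ev)
  if (!(is.finite(mn) && mn > M$mercer_tol * mx))
    stop(sprintf(paste0("stored patterns are not linearly independent in feature ",
                        "space (strong-Mercer check failed: min/max Gram eigenvalue ",
                        "= %.3e/%.3e, tol = %.1e)"), mn, mx, M$mercer_tol))
  M$ridge <- 0
  if (mx / mn > M$max_condition) {
    M$ridge <- 1e-10 * sum(diag(M$gram)) / M$m
    warning(sprintf("ill-conditioned Gram (condition %.2e); adding ridge %.2e",
                    mx / mn, M$ridge))
  }
  M$gram_factor <- chol(M$gram + diag(M$ridge, M$m))
  M
}

## Solve gram %*% C = H through the cached Cholesky factor.
.rekam_solve <- function(M, H) {
  backsolve(M$gram_factor, forwardsolve(M$gram_factor, H, upper.tri = TRUE, transpose = TRUE))
}

## Scaled kernel responses of the memory to probe columns Y: m x q matrix.
.rekam_response <- function(M, Y) {
  Y <- .as_pattern_matrix(Y)
  if (nrow(Y) != M$n) stop("probe dimension mismatch")
  if (M$kernel$family == "scalar_product") {
    H <- crossprod(M$attractors, Y)
    if (any(M$scales != 1)) stop("scaled recall requires a uniform kernel")
    return(H)
  }
  cf <- .kernel_coefs(M$kernel, M$n)
  D <- .wsqdist(M$attractors, Y, cf$a)
  if (M$scale_mode == "argument") {
    exp(-D / M$scales^2 - cf$b)
  } else {
    exp(-D - cf$b) / M$scales
  }
}

.squash <- function(M, Y) {
  if (M$activation == "clip") {
    Y[Y < M$box[1]] <- M$box[1]
    Y[Y > M$box[2]] <- M$box[2]
    Y
  } else {
    mid <- mean(M$box); half <- diff(M$box) / 2
    mid + half * tanh((Y - mid) / half)
  }
}

#' @export
print.rekam <- function(x, ...) {
  cat("Kernel associative memory\n")
  cat("  attractors:", x$m, "patterns of dimension", x$n, "\n")
  cat("  kernel:    "); print(x$kernel)
  if (any(x$scales != 1))
    cat("  scales:     range [", format(min(x$scales)), ",",
        format(max(x$scales)), "]\n")
  if (x$ridge > 0) cat("  ridge:     ", format(x$ridge), "\n")
  invisible(x)
}

#' @export
summary.rekam <- function(object, ...) {
  sm <- check_strong_mercer(object$kernel, object$attractors, object$mercer_tol)
  structure(list(n = object$n, m = object$m, kernel = object$kernel,
                 activation = object$activation, box = object$box,
                 scales = object$scales, labels = object$labels,
                 mercer = sm, ridge = object$ridge),
            class = "summary.rekam")
}

#' @export
print.summary.rekam <- function(x, ...) {
  cat("Kernel associative memory:", x$m, "attractors in dimension", x$n, "\n")
  print(x$kernel)
  cat("activation:", x$activation, " box: [", x$box[1], ",", x$box[2], "]\n")
  cat(sprintf("Gram eigenvalues: min %.3e, max %.3e (condition %.3e)\n",
              x$mercer$min_eigenvalue, x$mercer$max_eigenvalue,
              x$mercer$max_eigenvalue / x$mercer$min_eigenvalue))
  cat("strong-Mercer check:", if (x$mercer$ok) "passed" else "FAILED", "\n")
  if (any(x$scales != 1)) {
    cat("attraction-radius scales:\n"); print(summary(x$scales))
  }
  invisible(x)
}

#' @export
coef.rekam <- function(object, ...) object$attractors

#' Recall fixed points for new probe patterns
#'
#' Runs attractor recall from each column of `newdata` and reports the
#' converged pattern, the winning attractor, or the winner's label.
#'
#' @param object a [rekam()] memory.
#' @param newdata probe matrix (one probe per column) or a single vector.
#' @param type `"winner"` (attractor indices), `"label"` (winner labels),
#'   or `"pattern"` (matrix of converged patterns).
#' @param ... passed to [recall()] (`stop_threshold`, `max_iter`).
#' @export
predict.rekam <- function(object, newdata = NULL,
                          type = c("winner", "label", "pattern"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$attractors
  res <- recall_batch(object, newdata, ...)
  switch(type,
         winner = res$winner,
         label = {
           if (is.null(object$labels)) stop("memory has no attractor labels")
           object$labels[res$winner]
         },
         pattern = res$patterns)
}

#' Simulate noisy recall trials
#'
#' Draws probes by adding white noise to stored attractors and recalls
#' each, the elementary trial of the behavioral simulations.
#'
#' @param object a [rekam()] memory.
#' @param nsim trials per attractor.
#' @param seed optional RNG seed.
#' @param noise_frac noise standard deviation as a fraction of the
#'   pooled standard deviation of the stored patterns (default 0.1,
#'   i.e. 10 % of data STD).
#' @param ... passed to [recall_batch()].
#' @return data frame with columns `source`, `winner`, `correct`,
#'   `iterations`, `converged`.
#' @export
simulate.rekam <- function(object, nsim = 1, seed = NULL, noise_frac = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  src <- rep(seq_len(object$m), times = nsim)
  sdev <- stats::sd(as.vector(object$attractors)) * noise_frac
  Y0 <- object$attractors[, src, drop = FALSE] +
    matrix(stats::rnorm(object$n * length(src), sd = sdev), object$n)
  res <- recall_batch(object, Y0, ...)
  data.frame(source = src, winner = res$winner, correct = res$winner == src,
             iterations = res$iterations, converged = res$converged)
}

#' Plot a kernel memory
#'
#' `what = "gram"` draws the Gram matrix as a heat map (structure of
#' pairwise attractor similarity); `what = "scales"` the per-attractor
#' attraction-radius scales.
#'
#' @param x a [rekam()] memory.
#' @param what `"gram"` or `"scales"`.
#' @param ... further arguments to the underlying base-graphics call.
#' @export
plot.rekam <- function(x, what = c("gram", "scales"), ...) {
  what <- match.arg(what)
  if (what == "gram") {
    graphics::image(seq_len(x$m), seq_len(x$m), x$gram[, x$m:1, drop = FALSE],
                    xlab = "attractor", ylab = "attractor",
                    main = "Gram matrix", col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    ...)
  } else {
    graphics::barplot(x$scales, names.arg = seq_len(x$m),
                      xlab = "attractor", ylab = expression(lambda),
                      main = "attraction-radius scales", ...)
  }
  invisible(x)
}
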