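#' One recall iteration
#'
#' Applies the kernel-memory recall map once: scaled kernel responses
#' \eqn{h}, linear solve \eqn{G c = h}, readout \eqn{X c}, activation.
#'
#' @param M a [rekam()] memory.
#' @param y probe vector (length `M$n`) or matrix of probe columns.
#' @return pattern of the same shape as `y`.
#' @export
recall_step <- function(M, y) {
  vec <- is.vector(y)
  H <- .rekam_response(M, y)
  out <- .squash(M, M$attractors %*% .rekam_solve(M, H))
  if (vec) drop(out) else out
}

#' Iterative attractor recall
#'
#' Iterates [recall_step()] from `y0` until the max-norm update falls
#' below `stop_threshold` or `max_iter` is reached.
#'
#' @param M a [rekam()] memory.
#' @param y0 initial probe vector.
#' @param stop_threshold stop when `max(abs(update))` is below this.
#' @param max_iter iteration cap; on hitting it the best (last) iterate
#'   is returned with `converged = FALSE`.
#' @param trajectory keep the list of iterates?
#' @return an object of class `"rekam_recall"`: list with `pattern`
#'   (the fixed point), `winner` (index of the attractor with the
#'   largest scaled response to the final pattern), `iterations`,
#'   `converged`, and optionally `trajectory`.
#' @export
recall <- function(M, y0, stop_threshold = 1e-6, max_iter = 100, trajectory = FALSE) {
  y <- as.numeric(y0)
  if (length(y) != M$n) stop("probe dimension mismatch")
  traj <- if (trajectory) list(y) else NULL
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    y1 <- recall_step(M, y)
    delta <- max(abs(y1 - y))
    y <- y1
    if (trajectory) traj[[it + 1L]] <- y
    if (delta < stop_threshold) { converged <- TRUE; break }
  }
  structure(list(pattern = y, winner = nearest_attractor(M, y),
                 iterations = it, converged = converged,
                 trajectory = traj),
            class = "rekam_recall")
}

#' @export
print.rekam_recall <- function(x, ...) {
  cat("Recall:", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iteration(s); winner = attractor", x$winner, "\n")
  invisible(x)
}

#' Batched attractor recall
#'
#' Vectorized form of [recall()] over the columns of `Y0`; used by the
#' behavioral simulations, where thousands of probes are recalled
#' against the same memory.
#'
#' @inheritParams recall
#' @param Y0 matrix of probes, one per column.
#' @return list with `patterns` (matrix of fixed points), and vectors
#'   `winner`, `iterations`, `converged`.
#' @export
recall_batch <- function(M, Y0, stop_threshold = 1e-6, max_iter = 100) {
  Y <- .as_pattern_matrix(Y0)
  q <- ncol(Y)
  active <- rep(TRUE, q)
  iters <- integer(q)
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    Ya <- Y[, active, drop = FALSE]
    Y1 <- recall_step(M, Ya)
    delta <- apply(abs(Y1 - Ya), 2L, max)
    Y[, active] <- Y1
    iters[active] <- it
    done <- delta < stop_threshold
    active[active] <- !done
  }
  list(patterns = Y,
       winner = apply(.rekam_response(M, Y), 2L, which.max),
       iterations = iters,
       converged = !active)
}

#' Index of the attractor with the largest scaled response
#'
#' The winner readout: maximizes the (radius-scaled) kernel response to
#' `y`; exact ties break to the lowest index.
#'
#' @param M a [rekam()] memory.
#' @param y probe vector.
#' @export
nearest_attractor <- function(M, y) {
  which.max(.rekam_response(M, matrix(as.numeric(y), ncol = 1L)))
}
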