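#' Reconsolidate a memory toward a new stimulus
#'
#' Implements the reconsolidation update: the stimulus is recalled, the
#' winning attractor is identified, and the memory moves a fraction
#' `step` of the way toward the state in which that attractor is
#' replaced by the stimulus.
#'
#' \describe{
#'   \item{`mode = "exact_geodesic"`}{the update travels along the
#'     geodesic of the memory manifold ([geodesic_point()] at fraction
#'     `step`): a \emph{global} update — all attractors may shift,
#'     which is what produces gang-like co-updates of similar memories.}
#'   \item{`mode = "approximate"`}{the geodesic is replaced by a
#'     straight line in coordinate space: only the winning column moves,
#'     to \eqn{(1-\varepsilon) x_j + \varepsilon s}.  With
#'     `gang_size = L > 1` the \eqn{L} attractors with the largest
#'     scaled responses \eqn{h_j} each move with per-attractor step
#'     \eqn{\varepsilon_j = \varepsilon\, h_j / h_{(1)}} (the winner
#'     moves with the full step).  The coordinate shortcut deviates from
#'     the geodesic by \eqn{O(s^2)} in the stimulus displacement
#'     \eqn{s}.}
#' }
#'
#' Every update appends a row to `M$journal` recording the winner, the
#' step, and the "surprise" — the manifold distance between the current
#' memory and the stimulus-substituted one.  Surprise is logged, never
#' used to gate the update; gating policies are left to the caller.
#'
#' @param M a [rekam()] memory.
#' @param stimulus new stimulus vector (length `M$n`).
#' @param step update step \eqn{\varepsilon \in [0, 1]}: 0 leaves the
#'   memory unchanged, 1 replaces the recalled attractor outright.
#' @param mode `"approximate"` (default) or `"exact_geodesic"`.
#' @param gang_size number of attractors co-updated in approximate mode
#'   (\eqn{L \ge 1}; ignored by the exact mode, which is global anyway).
#' @param opts optimizer options for the exact mode (see
#'   [geodesic_point()]).
#' @param recall_args list of arguments passed to [recall()] for the
#'   stimulus (e.g. `stop_threshold`, `max_iter`).
#' @return the updated memory.  If the stimulus recall does not
#'   converge, the memory is returned unchanged with a warning.
#' @seealso [gang_reconsolidate()], [extinguish()], [geodesic_point()]
#' @export
reconsolidate <- function(M, stimulus, step,
                          mode = c("approximate", "exact_geodesic"),
                          gang_size = 1L, opts = list(), recall_args = list()) {
  stopifnot(inherits(M, "rekam"))
  mode <- match.arg(mode)
  stimulus <- as.numeric(stimulus)
  if (length(stimulus) != M$n) stop("stimulus dimension mismatch")
  if (step < 0 || step > 1) stop("'step' must lie in [0, 1]")
  gang_size <- as.integer(gang_size)
  if (gang_size < 1L || gang_size > M$m) stop("'gang_size' must be in 1..m")

  r <- do.call(recall, c(list(M, stimulus), recall_args))
  if (!r$converged) {
    warning("stimulus recall did not converge; memory left unchanged")
    return(M)
  }
  j <- r$winner

  X1 <- replace_attractor(M, j, stimulus)
  surprise <- memory_distance(M, X1)
  journal_row <- data.frame(winner = j, step = step, mode = mode,
                            surprise = surprise)

  out <- if (step == 0 || surprise == 0) {
    M
  } else if (mode == "exact_geodesic") {
    sol <- geodesic_point(M, X1, step, opts = opts)
    sol$point
  } else {
    h <- drop(.rekam_response(M, matrix(stimulus, ncol = 1L)))
    sel <- order(h, decreasing = TRUE)[seq_len(gang_size)]
    if (!(j %in% sel)) sel[gang_size] <- j
    upd <- M
    for (i in sel) {
      eps_i <- step * h[i] / h[j]
      upd <- replace_attractor(upd, i,
                               (1 - eps_i) * M$attractors[, i] + eps_i * stimulus)
    }
    upd
  }
  out$journal <- rbind(M$journal, journal_row)
  out
}

#' @export
update.rekam <- function(object, stimulus, step,
                         mode = c("approximate", "exact_geodesic"),
                         gang_size = 1L, ...) {
  reconsolidate(object, stimulus, step, mode = mode, gang_size = gang_size, ...)
}

#' Gang-effect reconsolidation
#'
#' Convenience wrapper for the multi-attractor approximate update: the
#' `gang_size` most responsive attractors all move toward the stimulus,
#' with steps proportional to their kernel responses.  With
#' `gang_size = 1` this is exactly the plain approximate update.
#'
#' @inheritParams reconsolidate
#' @param weighting optional function `(h, winner)` returning the
#'   per-attractor step multipliers in \eqn{[0, 1]}; the default is
#'   proportional-to-response, \eqn{h_j / h_{(1)}}.
#' @export
gang_reconsolidate <- function(M, stimulus, step, gang_size = 2L,
                               weighting = NULL, recall_args = list()) {
  if (is.null(weighting))
    return(reconsolidate(M, stimulus, step, mode = "approximate",
                         gang_size = gang_size, recall_args = recall_args))
  ## pluggable weighting: same selection, custom step multipliers
  stopifnot(inherits(M, "rekam"))
  stimulus <- as.numeric(stimulus)
  r <- do.call(recall, c(list(M, stimulus), recall_args))
  if (!r$converged) {
    warning("stimulus recall did not converge; memory left unchanged")
    return(M)
  }
  j <- r$winner
  h <- drop(.rekam_response(M, matrix(stimulus, ncol = 1L)))
  sel <- order(h, decreasing = TRUE)[seq_len(gang_size)]
  if (!(j %in% sel)) sel[gang_size] <- j
  wts <- weighting(h, j)
  upd <- M
  for (i in sel) {
    eps_i <- step * wts[i]
    upd <- replace_attractor(upd, i,
                             (1 - eps_i) * M$attractors[, i] + eps_i * stimulus)
  }
  upd
}

#' One extinction event
#'
#' A reactivation of attractor `i` without reinforcement: its
#' attraction-radius scale is multiplied by `decay` (default 0.7),
#' shrinking the basin.
#'
#' @param M a [rekam()] memory with a uniform kernel.
#' @param i attractor index.
#' @param decay multiplicative factor in \eqn{(0, 1)}.
#' @export
extinction_event <- function(M, i, decay = 0.7) {
  if (decay <= 0 || decay >= 1) stop("'decay' must lie in (0, 1)")
  set_scale(M, i, M$scales[i] * decay)
}

#' Extinction schedule with retrieval-probability curve
#'
#' Walks attractor `i`'s attraction-radius scale down a decreasing
#' schedule of \eqn{\lambda} values; at each value the retrieval
#' frequency of that attractor is estimated by recalling `n_queries`
#' random probes drawn uniformly from the data bounding box.  The same
#' probes are reused at every schedule point (common random numbers), so
#' the curve is monotone apart from genuine dynamics effects.
#'
#' Retrieval is measured, per probe, as the attractor winning the
#' radius-scaled kernel response (`readout = "response"`, the default):
#' for probes inside a basin this is the recall outcome, and it remains
#' a meaningful "which memory does this input activate" measure for
#' probes far outside every basin, where the iterative recall limit is
#' dominated by the global geometry of the stored set rather than by
#' the probe.  `readout = "recall"` runs full iterative recall instead.
#'
#' @param M a [rekam()] memory with a uniform kernel.
#' @param i index of the attractor being extinguished.
#' @param schedule decreasing vector of scale values \eqn{\lambda}.
#' @param n_queries probes per schedule point (default 1000).
#' @param seed optional RNG seed for the probe draw.
#' @param queries optional pre-drawn probe matrix (one per column),
#'   overriding the uniform draw.
#' @param readout `"response"` (default) or `"recall"`; see Details.
#' @return list with `memory` (the memory at the final schedule value)
#'   and `curve`, a data frame with columns `lambda` and `frequency`.
#' @export
extinguish <- function(M, i, schedule, n_queries = 1000, seed = NULL,
                       queries = NULL, readout = c("response", "recall")) {
  stopifnot(inherits(M, "rekam"))
  readout <- match.arg(readout)
  if (!is_uniform(M$kernel))
    stop("extinction requires a uniform kernel")
  if (is.unsorted(rev(schedule)) || any(schedule <= 0))
    stop("'schedule' must be a decreasing sequence of positive scales")
  if (is.null(queries)) {
    if (!is.null(seed)) set.seed(seed)
    lo <- apply(M$attractors, 1L, min)
    hi <- apply(M$attractors, 1L, max)
    queries <- matrix(stats::runif(M$n * n_queries, lo, hi), M$n)
  }
  freq <- numeric(length(schedule))
  for (k in seq_along(schedule)) {
    M <- set_scale(M, i, schedule[k])
    w <- if (readout == "recall") recall_batch(M, queries)$winner
         else apply(.rekam_response(M, queries), 2L, which.max)
    freq[k] <- mean(w == i)
  }
  list(memory = M, curve = data.frame(lambda = schedule, frequency = freq))
}
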