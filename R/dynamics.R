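#' Configuration of the continuous-time recall dynamics
#'
#' @param rates per-unit relaxation rates \eqn{\Lambda} (positive;
#'   recycled to the pattern dimension).  Default 1 for every unit.
#' @param horizon integration time \eqn{T > 0} (default 50).
#' @param dt solver step (default 0.05).  The explicit Euler scheme
#'   requires \eqn{dt < 2/\max\Lambda}.
#' @param solver `"rk4"` (default) or `"euler"`.
#' @return an object of class `"dynamics_config"`.
#' @export
dynamics_config <- function(rates = 1, horizon = 50, dt = 0.05,
                            solver = c("rk4", "euler")) {
  solver <- match.arg(solver)
  if (any(rates <= 0)) stop("relaxation rates must be positive")
  if (horizon <= 0 || dt <= 0) stop("'horizon' and 'dt' must be positive")
  structure(list(rates = rates, horizon = horizon, dt = dt, solver = solver),
            class = "dynamics_config")
}

#' Continuous-time attractor recall
#'
#' Integrates the firing-rate relaxation dynamics
#' \deqn{\dot y = \Lambda \odot (-y + F(y)),}
#' where \eqn{F} is one application of the discrete recall map
#' ([recall_step()]: kernel response, Gram solve, readout, activation).
#' By construction the discrete recall iterates are exactly the Euler
#' steps of this system with \eqn{\Lambda\, dt = 1}, so the two
#' formulations share their fixed points: equilibria of the flow are
#' the discrete recall fixed points and vice versa.  For the
#' scalar-product kernel with unit scales the system is the
#' continuous-time Hopfield network under the pseudoinverse (projection)
#' learning rule — see [hopfield_equivalence_check()].
#'
#' @param M a [rekam()] memory.
#' @param y0 initial state (length `M$n`).
#' @param cfg a [dynamics_config()].
#' @return an object of class `"rekam_trajectory"`: list with `times`,
#'   `states` (pattern per column), and `final`.
#' @export
continuous_recall <- function(M, y0, cfg = dynamics_config()) {
  stopifnot(inherits(M, "rekam"), inherits(cfg, "dynamics_config"))
  y <- as.numeric(y0)
  if (length(y) != M$n) stop("initial state dimension mismatch")
  lam <- rep_len(cfg$rates, M$n)
  if (cfg$solver == "euler" && cfg$dt >= 2 / max(lam))
    stop("explicit Euler is unstable: need dt < 2/max(rates)")
  steps <- ceiling(cfg$horizon / cfg$dt)
  states <- matrix(NA_real_, M$n, steps + 1L)
  states[, 1L] <- y
  f <- function(y) lam * (recall_step(M, y) - y)
  h <- cfg$dt
  for (k in seq_len(steps)) {
    y <- if (cfg$solver == "euler") {
      y + h * f(y)
    } else {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    states[, k + 1L] <- y
  }
  structure(list(times = seq(0, by = h, length.out = steps + 1L),
                 states = states, final = y),
            class = "rekam_trajectory")
}

#' @export
print.rekam_trajectory <- function(x, ...) {
  cat("Continuous recall trajectory:", ncol(x$states) - 1L, "steps to t =",
      max(x$times), "\n")
  invisible(x)
}

#' Pseudoinverse (projection-rule) Hopfield weight matrix
#'
#' \eqn{W = X X^+}: the orthogonal projector onto the column span of
#' `X`, the synaptic matrix of the pseudoinverse-learning Hopfield
#' memory.  Requires linearly independent columns.
#'
#' @param X pattern matrix, one stored pattern per column.
#' @return symmetric idempotent \eqn{n \times n} matrix of rank
#'   `ncol(X)`.
#' @export
hopfield_pseudoinverse <- function(X) {
  X <- .as_pattern_matrix(X)
  C <- crossprod(X)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("columns of 'X' are not linearly independent")
  W <- X %*% solve(C, t(X))
  (W + t(W)) / 2
}

#' Continuous kernel memory vs pseudoinverse Hopfield network
#'
#' For the scalar-product kernel with unit scales, the continuous-time
#' kernel memory is the Hopfield system
#' \eqn{\dot y = \Lambda \odot (-y + \sigma(W y))} with \eqn{W} from
#' [hopfield_pseudoinverse()]: the kernel readout
#' \eqn{X G^{-1} X^\top y} is algebraically \eqn{X X^+ y}.  This
#' routine integrates both systems from `y0` with the same solver and
#' returns the maximum state deviation along the trajectory (expected
#' at roundoff level, below `1e-8`, unless the memory carries a
#' conditioning ridge).
#'
#' @param M a [rekam()] memory with the `scalar_product` kernel and all
#'   scales equal to 1.
#' @param y0 initial state.
#' @param cfg a [dynamics_config()].
#' @return the maximum absolute deviation between the two trajectories.
#' @export
hopfield_equivalence_check <- function(M, y0, cfg = dynamics_config()) {
  stopifnot(inherits(M, "rekam"))
  if (M$kernel$family != "scalar_product")
    stop("the Hopfield equivalence holds for the scalar-product kernel")
  if (any(M$scales != 1)) stop("all attraction-radius scales must be 1")
  tr_kam <- continuous_recall(M, y0, cfg)

  W <- hopfield_pseudoinverse(M$attractors)
  lam <- rep_len(cfg$rates, M$n)
  y <- as.numeric(y0)
  f <- function(y) lam * (drop(.squash(M, W %*% y)) - y)
  h <- cfg$dt
  steps <- ceiling(cfg$horizon / cfg$dt)
  dev <- max(abs(y - tr_kam$states[, 1L]))
  for (k in seq_len(steps)) {
    y <- if (cfg$solver == "euler") {
      y + h * f(y)
    } else {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    dev <- max(dev, max(abs(y - tr_kam$states[, k + 1L])))
  }
  dev
}
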