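## ---- Riemannian structure on memory states -------------------------------
##
## A kernel memory with m attractors corresponds to the orthogonal
## projector onto the span of the attractors' feature images.  The
## Frobenius distance between two such projectors can be computed purely
## through kernel evaluations: with cross-kernel matrix K = K_XY and
## Gram matrices G_X, G_Y, the matrix
##
##     Pi = G_X^{-1} K G_Y^{-1} K^T
##
## has eigenvalues cos^2(theta_k), the squared principal cosines between
## the two feature subspaces.  Then
##
##     chordal:    d^2 = 2m - 2 sum cos^2 theta_k = 2 sum sin^2 theta_k
##     intrinsic:  d^2 = 2 sum theta_k^2     (arc length of the geodesic)
##
## The chordal form is exactly ||P_X - P_Y||_F (the embedding metric);
## the intrinsic form is the induced geodesic distance, which on the
## scalar-product kernel reduces to the standard Grassmann arc length.

.same_geometry <- function(M1, M2) {
  stopifnot(inherits(M1, "rekam"), inherits(M2, "rekam"))
  if (M1$m != M2$m) stop("memories store different numbers of attractors")
  if (M1$n != M2$n) stop("memories have different pattern dimensions")
  k1 <- M1$kernel; k2 <- M2$kernel
  same <- identical(k1$family, k2$family) &&
    isTRUE(all.equal(k1$sigma_v, k2$sigma_v)) &&
    isTRUE(all.equal(k1$sigma_r, k2$sigma_r)) &&
    isTRUE(all.equal(k1$weights, k2$weights)) &&
    isTRUE(all.equal(k1$bias, k2$bias))
  if (!same) stop("memories use different kernels")
  invisible(TRUE)
}

## Squared principal cosines between the feature spans of M1 and M2,
## clipped into [0, 1].
.principal_cosines <- function(M1, M2) {
  K <- .cross_kernel(M1$kernel, M1$attractors, M2$attractors)
  A <- K %*% .rekam_solve(M2, t(K))          # K G_Y^{-1} K^T
  R <- M1$gram_factor                        # G_X = R^T R
  T1 <- backsolve(R, A, transpose = TRUE)    # R^{-T} A
  S <- t(backsolve(R, t(T1), transpose = TRUE))
  lam <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  pmin(pmax(lam, 0), 1)
}

#' Distance between two memory states
#'
#' Both memories must store the same number of attractors with the same
#' kernel.  `method = "chordal"` (default) returns the Frobenius norm of
#' the difference of the two feature-space projectors, evaluated
#' entirely through kernel calls; it lies in \eqn{[0, \sqrt{2m}]}.  For
#' the scalar-product kernel it equals
#' \eqn{\|X X^+ - Y Y^+\|_F} exactly.  `method = "intrinsic"` returns
#' the induced geodesic (arc-length) distance
#' \eqn{\sqrt{2 \sum_k \theta_k^2}} built from the principal angles
#' \eqn{\theta_k} between the two feature subspaces; this is the
#' distance whose weighted Fréchet minimizer reproduces geodesic
#' interpolation, and the one used internally by [geodesic_point()].
#'
#' The distance between a memory and the memory obtained by replacing
#' the recalled attractor with a new stimulus measures the "surprise"
#' the stimulus causes; [reconsolidate()] logs it at every update.
#'
#' @param M1,M2 [rekam()] memories of identical geometry.
#' @param method `"chordal"` or `"intrinsic"`.
#' @return a nonnegative number.
#' @export
memory_distance <- function(M1, M2, method = c("chordal", "intrinsic")) {
  method <- match.arg(method)
  .same_geometry(M1, M2)
  lam <- .principal_cosines(M1, M2)
  if (method == "chordal") sqrt(max(0, 2 * sum(1 - lam)))
  else sqrt(2 * sum(acos(sqrt(lam))^2))
}

#' Greedy response alignment of two attractor sets
#'
#' Pairs each attractor of `M1` with its most kernel-similar attractor
#' in `M2` (greedy, largest responses first).  Used before geodesic
#' optimization so the coordinate-space initialization does not suffer
#' from permutation ambiguity.
#'
#' @param M1,M2 [rekam()] memories of identical geometry.
#' @return integer permutation `p` such that column `j` of `M1` pairs
#'   with column `p[j]` of `M2`.
#' @export
align_attractors <- function(M1, M2) {
  .same_geometry(M1, M2)
  K <- .cross_kernel(M1$kernel, M1$attractors, M2$attractors)
  m <- ncol(K)
  p <- integer(m)
  for (step in seq_len(m)) {
    ij <- arrayInd(which.max(K), dim(K))
    p[ij[1L]] <- ij[2L]
    K[ij[1L], ] <- -Inf
    K[, ij[2L]] <- -Inf
  }
  p
}

## Intrinsic squared distance from the attractor set Z to the fixed
## memory M, with its gradient in Z.  Derivation: lambda_k are the
## generalized eigenvalues of (K G_X^{-1} K^T, G_Z) with eigenvectors
## normalized u^T G_Z u = 1; first-order perturbation gives
## d lambda_k = u_k' dA u_k - lambda_k u_k' dG_Z u_k, and the kernel
## derivatives contract as in .kernel_grad_contract.  g(lambda) =
## arccos(sqrt(lambda))^2 with g'(lambda) = -2 theta / sin(2 theta).
.dist2_intrinsic_grad <- function(spec, Z, M, want_grad = TRUE) {
  m <- ncol(Z)
  G_Z <- gram_matrix(spec, Z)
  R <- tryCatch(chol(G_Z), error = function(e) NULL)
  if (is.null(R)) return(list(value = Inf, grad = NULL))
  K <- .cross_kernel(spec, Z, M$attractors)
  A <- K %*% .rekam_solve(M, t(K))
  T1 <- backsolve(R, A, transpose = TRUE)
  S <- t(backsolve(R, t(T1), transpose = TRUE))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmin(pmax(es$values, 1e-12), 1)
  theta <- acos(sqrt(lam))
  value <- 2 * sum(theta^2)
  if (!want_grad) return(list(value = value, grad = NULL))
  gp <- ifelse(theta < 1e-6, -1, -2 * theta / pmax(sin(2 * theta), 1e-12))
  U <- backsolve(R, es$vectors)              # u^T G_Z u = I
  B <- .rekam_solve(M, t(K)) %*% U           # G_X^{-1} K^T U
  W1 <- 4 * (U %*% (gp * t(B)))              # d f / d K_ij
  W2 <- -4 * (U %*% (gp * lam * t(U)))       # contraction weights for dG
  grad <- .kernel_grad_contract(spec, Z, M$attractors, W1, K) +
    .kernel_grad_contract(spec, Z, Z, W2, G_Z)
  list(value = value, grad = grad)
}

#' Geodesic interpolation between two memory states
#'
#' Finds the memory state a fraction `t` of the way along the geodesic
#' from `M1` to `M2` on the manifold of kernel memories, by minimizing
#' the weighted Fréchet objective
#' \deqn{J(Z) = (1 - t)\, d(M_1, Z)^2 + t\, d(M_2, Z)^2}
#' over the \eqn{m} attractor columns of \eqn{Z}, where \eqn{d} is the
#' intrinsic (principal-angle) distance of [memory_distance()].  The
#' minimizer of this objective lies on the connecting geodesic and
#' splits it with proportions \eqn{t : (1-t)}; for the scalar-product
#' kernel this reproduces closed-form Grassmann geodesics.  The search
#' is initialized at the coordinate-space convex combination
#' \eqn{(1-t) X_1 + t X_2} after greedy column alignment.
#'
#' @param M1,M2 [rekam()] memories of identical geometry.
#' @param t interpolation fraction in \eqn{[0, 1]}; `t = 0` returns
#'   `M1`, `t = 1` returns `M2`.
#' @param opts optional list: `method` (`"bfgs"`, the default, uses the
#'   analytic gradient of the objective; `"nelder_mead"` is a
#'   derivative-free fallback), `maxit` (default 500), `reltol`
#'   (default `1e-12`), `align` (default `TRUE`), and `chart_penalty`
#'   (default `1e-4`): the attractor-coordinate chart of the memory
#'   manifold has gauge directions — column changes that barely move
#'   the feature span, exactly flat for the scalar-product kernel and
#'   nearly flat whenever attractors crowd together — so a small
#'   quadratic pull `chart_penalty * ||Z - Z0||^2` toward the
#'   initialization selects the minimum-motion parametrization of the
#'   optimum.  It regularizes the chart, not the geometry; set it to 0
#'   for the unpenalized objective.
#' @return an object of class `"rekam_geodesic"`: list with `point`
#'   (the interpolated [rekam()] memory), `t`, `objective`, `d_left`,
#'   `d_right` (chordal distances to the endpoints), `iterations`, and
#'   `converged`.
#' @seealso [distance_split()], [reconsolidate()]
#' @export
geodesic_point <- function(M1, M2, t, opts = list()) {
  .same_geometry(M1, M2)
  if (t < 0 || t > 1) stop("'t' must lie in [0, 1]")
  method <- if (is.null(opts$method)) "bfgs" else match.arg(opts$method, c("bfgs", "nelder_mead"))
  maxit  <- if (is.null(opts$maxit)) 500L else opts$maxit
  reltol <- if (is.null(opts$reltol)) 1e-12 else opts$reltol
  align  <- if (is.null(opts$align)) TRUE else opts$align
  mu     <- if (is.null(opts$chart_penalty)) 1e-4 else opts$chart_penalty

  finish <- function(Z, objective, iterations, converged) {
    box <- range(M1$box, Z)
    point <- rekam(Z, kernel = M1$kernel, scales = M1$scales,
                   labels = M1$labels, list_tags = M1$list_tags,
                   activation = M1$activation, box = box,
                   scale_mode = M1$scale_mode,
                   mercer_tol = M1$mercer_tol, max_condition = M1$max_condition)
    structure(list(point = point, t = t, objective = objective,
                   d_left = memory_distance(M1, point),
                   d_right = memory_distance(point, M2),
                   iterations = iterations, converged = converged),
              class = "rekam_geodesic")
  }

  if (isTRUE(all.equal(M1$attractors, M2$attractors)) || t == 0)
    return(finish(M1$attractors, 0, 0L, TRUE))
  if (t == 1)
    return(finish(M2$attractors, 0, 0L, TRUE))

  X2 <- M2$attractors
  if (align) X2 <- X2[, align_attractors(M1, M2), drop = FALSE]
  Z0 <- (1 - t) * M1$attractors + t * X2
  n <- M1$n; m <- M1$m
  spec <- M1$kernel

  fn <- function(par) {
    Z <- matrix(par, n, m)
    v <- (1 - t) * .dist2_intrinsic_grad(spec, Z, M1, want_grad = FALSE)$value +
      t * .dist2_intrinsic_grad(spec, Z, M2, want_grad = FALSE)$value
    if (!is.finite(v)) return(1e10)
    v + mu * sum((Z - Z0)^2)
  }
  gr <- function(par) {
    Z <- matrix(par, n, m)
    g1 <- .dist2_intrinsic_grad(spec, Z, M1)
    g2 <- .dist2_intrinsic_grad(spec, Z, M2)
    if (!is.finite(g1$value) || !is.finite(g2$value)) return(rep(0, length(par)))
    as.vector((1 - t) * g1$grad + t * g2$grad + 2 * mu * (Z - Z0))
  }

  res <- if (method == "bfgs") {
    stats::optim(as.vector(Z0), fn, gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
  } else {
    stats::optim(as.vector(Z0), fn, method = "Nelder-Mead",
                 control = list(maxit = max(maxit, 2000L), reltol = reltol))
  }
  Zsol <- matrix(res$par, n, m)
  finish(Zsol, res$value - mu * sum((Zsol - Z0)^2),
         as.integer(res$counts[[1L]]), res$convergence == 0L)
}

#' @export
print.rekam_geodesic <- function(x, ...) {
  cat(sprintf("Geodesic point at t = %g (%s)\n", x$t,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  objective %.6g, d_left %.6g, d_right %.6g, split %.4f\n",
              x$objective, x$d_left, x$d_right,
              x$d_left / (x$d_left + x$d_right)))
  invisible(x)
}

#' Distances from a geodesic point to its endpoints
#'
#' Returns the (chordal) distances from the interpolated memory to the
#' two endpoints.  For a converged solution their ratio
#' `d_left / (d_left + d_right)` approximates the interpolation
#' fraction `t`.
#'
#' @param sol a `"rekam_geodesic"` solution from [geodesic_point()].
#' @return numeric vector `c(d_left, d_right)`.
#' @export
distance_split <- function(sol) {
  stopifnot(inherits(sol, "rekam_geodesic"))
  c(d_left = sol$d_left, d_right = sol$d_right)
}
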