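#' Principal-component preprocessing
#'
#' Fits a PCA transform on training patterns (one per column) and keeps
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target`.
#'
#' @param data training matrix, one pattern per column.
#' @param variance_target cumulative explained-variance fraction in
#'   \eqn{(0, 1]}.
#' @return an object of class `"pca_transform"`: list with `center`,
#'   `rotation` (loadings, one component per column), `k`,
#'   `explained` (per-component variance fractions) and `cumulative`.
#' @export
pca_fit <- function(data, variance_target = 0.9677) {
  data <- .as_pattern_matrix(data)
  if (variance_target <= 0 || variance_target > 1)
    stop("'variance_target' must lie in (0, 1]")
  p <- stats::prcomp(t(data), center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  frac <- v / sum(v)
  cum <- cumsum(frac)
  k <- which(cum >= variance_target - 1e-9)[1L]
  if (is.na(k)) k <- length(cum)
  structure(list(center = p$center,
                 rotation = p$rotation[, seq_len(k), drop = FALSE],
                 k = k, explained = frac, cumulative = cum,
                 variance_target = variance_target),
            class = "pca_transform")
}

#' @rdname pca_fit
#' @param transform a `"pca_transform"`.
#' @param x pattern vector or matrix of pattern columns.
#' @return reduced vector / matrix with `transform$k` rows.
#' @export
pca_apply <- function(transform, x) {
  stopifnot(inherits(transform, "pca_transform"))
  vec <- is.vector(x)
  x <- .as_pattern_matrix(x)
  out <- crossprod(transform$rotation, x - transform$center)
  if (vec) drop(out) else out
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("PCA transform: %d components (%.2f%% of variance, target %.2f%%)\n",
              x$k, 100 * x$cumulative[x$k], 100 * x$variance_target))
  invisible(x)
}
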