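#' Scale an attractor's basin of attraction
#'
#' Assigns attraction-radius scales \eqn{\lambda_i > 0}.  For a uniform
#' kernel the scaled response evaluates the kernel at the difference
#' \eqn{(x_i - y)/\lambda_i}, so the basin radius grows proportionally
#' to \eqn{\lambda_i}; driving \eqn{\lambda_i \to 0} makes attractor
#' \eqn{i} unreachable — the model's account of extinction.
#'
#' @param M a [rekam()] memory with a uniform kernel.
#' @param i attractor index (or vector of indices).
#' @param value new positive scale(s), recycled along `i`.
#' @return the updated memory.
#' @seealso [extinguish()] for a full extinction schedule.
#' @export
set_scale <- function(M, i, value) {
  stopifnot(inherits(M, "rekam"))
  if (!is_uniform(M$kernel))
    stop("attraction-radius scaling requires a uniform kernel")
  i <- as.integer(i)
  if (any(i < 1L | i > M$m)) stop("attractor index out of range")
  value <- rep_len(as.numeric(value), length(i))
  if (any(value <= 0)) stop("scales must be positive")
  M$scales[i] <- value
  M
}

## Shared tail of every attractor edit: bump the edit counter, do a full
## Gram recompute every 32 edits to bound incremental drift, recheck the
## strong-Mercer condition, refresh the factorization.
.after_edit <- function(M) {
  M$edits <- M$edits + 1L
  .rebuild_gram(M, full = M$edits %% 32L == 0L)
}

#' Edit the stored attractors
#'
#' `replace_attractor()` substitutes pattern `s` for attractor `i`;
#' `add_attractor()` appends a new attractor; `remove_attractor()`
#' deletes one.  The Gram matrix is updated incrementally (only the
#' affected row/column is re-evaluated), with a full recompute every 32
#' edits; each edit re-runs the strong-Mercer check and is refused if
#' the edited set would lose feature-space independence.
#'
#' @param M a [rekam()] memory.
#' @param i attractor index.
#' @param s replacement / new pattern (length `M$n`).
#' @param label,list_tag,scale metadata for the added attractor.
#' @return the updated memory.
#' @export
replace_attractor <- function(M, i, s) {
  stopifnot(inherits(M, "rekam"))
  i <- as.integer(i)
  if (i < 1L || i > M$m) stop("attractor index out of range")
  s <- as.numeric(s)
  if (length(s) != M$n) stop("pattern dimension mismatch")
  M$attractors[, i] <- s
  g <- kernel_vector(M$kernel, M$attractors, s)
  M$gram[i, ] <- g
  M$gram[, i] <- g
  .after_edit(M)
}

#' @rdname replace_attractor
#' @export
add_attractor <- function(M, s, label = NULL, list_tag = NULL, scale = 1) {
  stopifnot(inherits(M, "rekam"))
  s <- as.numeric(s)
  if (length(s) != M$n) stop("pattern dimension mismatch")
  g <- kernel_vector(M$kernel, M$attractors, s)
  gss <- eval_kernel(M$kernel, s, s)
  M$attractors <- cbind(M$attractors, s, deparse.level = 0)
  M$gram <- rbind(cbind(M$gram, g), c(g, gss))
  dimnames(M$gram) <- NULL
  M$m <- M$m + 1L
  M$scales <- c(M$scales, scale)
  if (!is.null(M$labels)) M$labels <- c(M$labels, if (is.null(label)) NA else label)
  if (!is.null(M$list_tags)) M$list_tags <- c(M$list_tags, if (is.null(list_tag)) NA else list_tag)
  .after_edit(M)
}

#' @rdname replace_attractor
#' @export
remove_attractor <- function(M, i) {
  stopifnot(inherits(M, "rekam"))
  i <- as.integer(i)
  if (i < 1L || i > M$m) stop("attractor index out of range")
  if (M$m == 1L) stop("cannot remove the last attractor")
  M$attractors <- M$attractors[, -i, drop = FALSE]
  M$gram <- M$gram[-i, -i, drop = FALSE]
  M$m <- M$m - 1L
  M$scales <- M$scales[-i]
  if (!is.null(M$labels)) M$labels <- M$labels[-i]
  if (!is.null(M$list_tags)) M$list_tags <- M$list_tags[-i]
  .after_edit(M)
}
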