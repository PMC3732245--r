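## ---- Synthetic stimuli ----------------------------------------------------
##
## The behavioral simulations run on procedurally generated images:
## smooth random "object images" (low-pass filtered noise) for the
## list-learning and extinction tasks, and stroke-drawn glyphs for the
## rotation-tracking task.  Everything is seeded and reproducible.

#' Smooth random object images
#'
#' Draws i.i.d. synthetic "object" images: white noise on a square
#' grid, low-pass filtered with a separable moving-average window, then
#' scaled to a common root-mean-square amplitude and clipped to
#' \eqn{[-1, 1]}.  The common amplitude keeps the stored items
#' exchangeable (comparable basin sizes and near-uniform retrieval under
#' random probes), and the smoothing gives the images the spatial
#' correlation structure of natural objects rather than of pixel noise.
#'
#' @param n_images number of images.
#' @param image_dim total pixel count; must be a perfect square
#'   (default 256 = 16 x 16).
#' @param smooth half-width of the moving-average window in pixels.
#' @param rms target root-mean-square amplitude (default 0.35).
#' @param seed optional RNG seed.
#' @return `image_dim` x `n_images` matrix, one image per column.
#' @export
gen_smooth_images <- function(n_images, image_dim = 256, smooth = 2,
                              rms = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- as.integer(round(sqrt(image_dim)))
  if (side * side != image_dim) stop("'image_dim' must be a perfect square")
  w <- 2L * as.integer(smooth) + 1L
  out <- matrix(NA_real_, image_dim, n_images)
  for (j in seq_len(n_images)) {
    img <- matrix(stats::rnorm(image_dim), side, side)
    ## separable moving average with replicated edges
    pad <- function(A, k) A[c(rep(1L, k), seq_len(nrow(A)), rep(nrow(A), k)), , drop = FALSE]
    sm <- function(A) {
      P <- pad(A, smooth)
      apply(P, 2L, function(col) stats::filter(col, rep(1 / w, w), sides = 2))[
        (smooth + 1L):(smooth + side), , drop = FALSE]
    }
    img <- t(sm(t(sm(img))))
    img <- img - mean(img)
    img <- img * (rms / sqrt(mean(img^2)))
    img[img > 1] <- 1; img[img < -1] <- -1
    out[, j] <- as.vector(img)
  }
  out
}

## ---- glyphs ---------------------------------------------------------------

## Stroke prototypes on the unit square, kept inside radius ~0.3 of the
## center so any rotation stays in frame.  Each row: x1 y1 x2 y2.
## The first five prototypes are rotation-asymmetric (no point
## symmetry), so classification under large rotations remains
## informative; point-symmetric shapes — which map onto themselves at
## 180 degrees and confound the classification measure the way
## symmetric digits do — come last.
.glyph_strokes <- function(class) {
  s <- switch(as.character(class),
    "1" = rbind(c(0.32, 0.24, 0.32, 0.76), c(0.32, 0.76, 0.74, 0.76)),        # L
    "2" = rbind(c(0.24, 0.26, 0.76, 0.26), c(0.50, 0.26, 0.50, 0.78)),        # T
    "3" = rbind(c(0.28, 0.26, 0.50, 0.78), c(0.50, 0.78, 0.72, 0.26)),        # V
    "4" = rbind(c(0.50, 0.24, 0.26, 0.70), c(0.26, 0.70, 0.74, 0.70),
                c(0.74, 0.70, 0.50, 0.24)),                                   # triangle
    "5" = rbind(c(0.34, 0.24, 0.34, 0.76), c(0.34, 0.76, 0.70, 0.76),
                c(0.34, 0.52, 0.62, 0.52)),                                   # F
    "6" = rbind(c(0.50, 0.22, 0.50, 0.78), c(0.22, 0.50, 0.78, 0.50)),        # plus
    "7" = rbind(c(0.50, 0.22, 0.50, 0.78)),                                   # bar
    "8" = rbind(c(0.26, 0.26, 0.74, 0.26), c(0.74, 0.26, 0.26, 0.74),
                c(0.26, 0.74, 0.74, 0.74)),                                   # Z
    "9" = rbind(c(0.30, 0.26, 0.30, 0.74), c(0.70, 0.26, 0.70, 0.74),
                c(0.30, 0.50, 0.70, 0.50)),                                   # H
    "10" = rbind(c(0.26, 0.30, 0.74, 0.70)),                                  # slash
    stop("no glyph prototype for class ", class))
  s
}

## Distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorized.
.seg_dist <- function(px, py, seg) {
  dx <- seg[3L] - seg[1L]; dy <- seg[4L] - seg[2L]
  len2 <- dx * dx + dy * dy
  tt <- ((px - seg[1L]) * dx + (py - seg[2L]) * dy) / max(len2, 1e-12)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (seg[1L] + tt * dx))^2 + (py - (seg[2L] + tt * dy))^2)
}

## Render jittered strokes to a size x size grayscale image in [0, 1].
.render_glyph <- function(strokes, size, stroke_width = 0.05) {
  g <- (seq_len(size) - 0.5) / size
  px <- rep(g, times = size)          # x varies fastest (column-major pixels)
  py <- rep(g, each = size)
  d <- rep(Inf, size * size)
  for (k in seq_len(nrow(strokes))) d <- pmin(d, .seg_dist(px, py, strokes[k, ]))
  matrix(exp(-d^2 / (2 * stroke_width^2)), size, size)
}

#' Rotate a grayscale image about its exact center
#'
#' Counterclockwise rotation by `theta` degrees with bilinear
#' interpolation; samples falling outside the frame read as the
#' background value 0.
#'
#' @param img numeric matrix (a square image).
#' @param theta rotation angle in degrees, counterclockwise.
#' @return matrix of the same dimension.
#' @export
rotate_image <- function(img, theta) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  th <- theta * pi / 180
  co <- cos(th); si <- sin(th)
  i <- rep(seq_len(nr), times = nc) - cx
  j <- rep(seq_len(nc), each = nr) - cy
  ## inverse map: source coordinates that land on (i, j)
  si0 <- co * i + si * j + cx
  sj0 <- -si * i + co * j + cy
  i0 <- floor(si0); j0 <- floor(sj0)
  fi <- si0 - i0; fj <- sj0 - j0
  val <- function(ii, jj) {
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    v <- numeric(length(ii))
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  out <- (1 - fi) * (1 - fj) * val(i0, j0) +
    fi * (1 - fj) * val(i0 + 1L, j0) +
    (1 - fi) * fj * val(i0, j0 + 1L) +
    fi * fj * val(i0 + 1L, j0 + 1L)
  matrix(out, nr, nc)
}

#' Configuration of the rotating-glyph tracking experiment
#'
#' Synthetic analogue of tracking slowly rotating handwritten digits:
#' procedurally drawn stroke glyphs (one prototype per class, jittered
#' per exemplar) are rotated counterclockwise in equal increments and
#' presented in angle order.
#'
#' @param n_classes number of glyph classes (max 10).
#' @param per_class exemplars per class.
#' @param angle_step rotation increment in degrees.
#' @param n_steps number of angle steps (angles `0, angle_step, ...`).
#' @param image_size image side length in pixels.
#' @param jitter per-exemplar control-point jitter (unit coordinates).
#' @param stroke_width stroke half-width (unit coordinates).
#' @param pca_variance_target cumulative explained-variance target of
#'   the principal-component preprocessing (default 0.9677).
#' @param sigma_factor data bandwidth of the tracking memory as a
#'   fraction of the median weighted attractor distance (default 0.7;
#'   below 1 so the recall map contracts briskly onto the attractors).
#' @param mode reconsolidation mode for [run_tracking()]:
#'   `"approximate"`, `"exact"`, or `"none"`.
#' @param shift_step reconsolidation step \eqn{\varepsilon}.
#' @param shuffle present stimuli in random order instead of increasing
#'   angle (gradualness control).
#' @param seed RNG seed.
#' @return an object of class `"rotation_config"`.
#' @export
rotation_config <- function(n_classes = 5, per_class = 4, angle_step = 4,
                            n_steps = 45, image_size = 24, jitter = 0.025,
                            stroke_width = 0.05,
                            pca_variance_target = 0.9677, sigma_factor = 0.7,
                            mode = c("approximate", "exact", "none"),
                            shift_step = 0.5, shuffle = FALSE, seed = 1) {
  mode <- match.arg(mode)
  structure(list(n_classes = n_classes, per_class = per_class,
                 angle_step = angle_step, n_steps = n_steps,
                 image_size = image_size, jitter = jitter,
                 stroke_width = stroke_width,
                 pca_variance_target = pca_variance_target,
                 sigma_factor = sigma_factor,
                 mode = mode, shift_step = shift_step,
                 shuffle = shuffle, seed = seed),
            class = "rotation_config")
}

#' Generate the rotating-glyph stimulus sequence
#'
#' Draws `n_classes * per_class` jittered base glyphs and rotates each
#' by every multiple of `angle_step`, producing
#' `n_classes * per_class * n_steps` stimuli ordered by increasing
#' angle.
#'
#' @param cfg a [rotation_config()].
#' @return list with `images` (pixels x stimuli matrix), `info`
#'   (data frame: `class`, `exemplar`, `angle`, `step`), `base`
#'   (pixels x exemplars matrix of unrotated glyphs), and `cfg`.
#' @export
gen_rotating_glyphs <- function(cfg) {
  stopifnot(inherits(cfg, "rotation_config"))
  set.seed(cfg$seed)
  S <- cfg$image_size
  n_ex <- cfg$n_classes * cfg$per_class
  base <- matrix(NA_real_, S * S, n_ex)
  cls <- rep(seq_len(cfg$n_classes), each = cfg$per_class)
  for (e in seq_len(n_ex)) {
    st <- .glyph_strokes(cls[e])
    st <- st + matrix(stats::rnorm(length(st), sd = cfg$jitter), nrow(st), 4L)
    base[, e] <- as.vector(.render_glyph(st, S, cfg$stroke_width))
  }
  angles <- (seq_len(cfg$n_steps) - 1L) * cfg$angle_step
  images <- matrix(NA_real_, S * S, n_ex * cfg$n_steps)
  info <- data.frame(class = integer(0), exemplar = integer(0),
                     angle = numeric(0), step = integer(0))
  col <- 0L
  for (k in seq_along(angles)) {
    for (e in seq_len(n_ex)) {
      col <- col + 1L
      img <- matrix(base[, e], S, S)
      images[, col] <- if (angles[k] == 0) base[, e] else
        as.vector(rotate_image(img, angles[k]))
      info[col, ] <- list(cls[e], e, angles[k], k)
    }
  }
  list(images = images, info = info, base = base, cfg = cfg)
}
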