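## ---- Behavioral simulations ----------------------------------------------

#' Configuration of the list-learning simulation
#'
#' Two groups learn two 20-item lists of synthetic object images.  Each
#' stored pattern carries an extra indicator channel \eqn{r \in [0,1]}
#' encoding association with the List-1 learning context (the "blue
#' basket"): List-1 items load at \eqn{r = 1}, List-2 items at
#' \eqn{r = 0}.  In the reminded group (A) every List-2 learning event
#' happens with the reminder present, which reconsolidates the item's
#' indicator toward 1 with step `shift_step`; the control group (B)
#' receives no reminder and no updates.  Memory is then tested in
#' recall mode with noisy probes of the List-1 items whose indicator is
#' set to the uncommitted initial value `r_init`; each recall is
#' classified by the winning attractor's list.
#'
#' @param items_per_list items per list (default 20).
#' @param image_dim pixels per object image (perfect square; default
#'   64).
#' @param smooth image smoothing half-width (default 3; heavier
#'   smoothing than the extinction images, giving the cross-item
#'   distance spread that makes intrusion rates graded rather than
#'   all-or-nothing).
#' @param noise_frac query noise standard deviation as a fraction of
#'   the pooled data standard deviation (default 0.10).
#' @param queries_per_list number of noisy probes per tested list
#'   (default 1000).
#' @param shift_step indicator shift \eqn{\varepsilon} applied at each
#'   reminded event (group A only).
#' @param n_reminded_events reminded events per List-2 item (default 1).
#' @param r_init indicator value of query vectors (default 0.5,
#'   uncommitted; the calibration sweep selects it).
#' @param sigma_v data-block bandwidth; default (`NULL`) uses the
#'   median pairwise image distance.
#' @param sigma_r indicator-channel bandwidth (default 1.1; soft
#'   relative to the unit indicator range, so the context channel
#'   biases rather than dominates the response).
#' @param readout winner readout for the test phase: `"response"`
#'   (default; the attractor with the largest kernel response to the
#'   probe — the package's winner readout) or `"recall"` (winner of
#'   full iterative recall).
#' @param seed RNG seed for the stimulus and query draws.
#' @return an object of class `"list_learning_config"`.
#' @export
list_learning_config <- function(items_per_list = 20, image_dim = 64,
                                 smooth = 3,
                                 noise_frac = 0.10, queries_per_list = 1000,
                                 shift_step = 0.3, n_reminded_events = 1,
                                 r_init = 0.5, sigma_v = NULL, sigma_r = 1.1,
                                 readout = "response", seed = 1) {
  if (r_init < 0 || r_init > 1) stop("'r_init' must lie in [0, 1]")
  structure(list(items_per_list = items_per_list, image_dim = image_dim,
                 smooth = smooth,
                 noise_frac = noise_frac, queries_per_list = queries_per_list,
                 shift_step = shift_step, n_reminded_events = n_reminded_events,
                 r_init = r_init, sigma_v = sigma_v, sigma_r = sigma_r,
                 readout = readout, seed = seed),
            class = "list_learning_config")
}

#' Generate the list-learning stimulus set
#'
#' Draws `2 * items_per_list` smooth random object images and augments
#' each with the list-context indicator channel (1 for List-1 items,
#' 0 for List-2 items at load time).
#'
#' @param cfg a [list_learning_config()].
#' @return list with `patterns` (`image_dim + 1` rows, indicator last),
#'   `images` (data block only), `list_tags` (1/2 per item), and `cfg`.
#' @export
gen_list_stimuli <- function(cfg) {
  stopifnot(inherits(cfg, "list_learning_config"))
  m <- 2L * cfg$items_per_list
  images <- gen_smooth_images(m, cfg$image_dim, smooth = cfg$smooth,
                              seed = cfg$seed)
  list_tags <- rep(1:2, each = cfg$items_per_list)
  indicator <- ifelse(list_tags == 1L, 1, 0)
  list(patterns = rbind(images, indicator, deparse.level = 0),
       images = images, list_tags = list_tags, cfg = cfg)
}

## Fixed query noise, drawn once per dataset so that every sweep point
## and both groups see identical probes (common random numbers).
.list_query_noise <- function(dataset) {
  cfg <- dataset$cfg
  set.seed(cfg$seed + 1000L)
  sdev <- stats::sd(as.vector(dataset$images)) * cfg$noise_frac
  lapply(1:2, function(tl) {
    items <- which(dataset$list_tags == tl)
    src <- rep_len(items, cfg$queries_per_list)
    noise <- matrix(stats::rnorm(cfg$image_dim * cfg$queries_per_list, sd = sdev),
                    cfg$image_dim)
    list(src = src, noise = noise)
  })
}

## Build the group memory: load all 40 patterns, then (group A) apply
## the reminded-event indicator updates to every List-2 attractor.
.list_memory <- function(dataset, cfg, reminded) {
  sv <- if (is.null(cfg$sigma_v)) median_bandwidth(dataset$images) else cfg$sigma_v
  ks <- kernel_spec("gaussian_indicator", sigma_v = sv, sigma_r = cfg$sigma_r)
  M <- rekam(dataset$patterns, kernel = ks, list_tags = dataset$list_tags)
  if (reminded && cfg$shift_step > 0) {
    idx <- which(dataset$list_tags == 2L)
    for (ev in seq_len(cfg$n_reminded_events)) {
      for (i in idx) {
        s <- M$attractors[, i]
        s[M$n] <- (1 - cfg$shift_step) * s[M$n] + cfg$shift_step * 1
        M <- replace_attractor(M, i, s)
      }
    }
  }
  M
}

## Recall percentages for one group on one tested list.
.list_test <- function(M, dataset, cfg, qn, test_list) {
  q <- qn[[test_list]]
  Q <- rbind(dataset$images[, q$src, drop = FALSE] + q$noise,
             cfg$r_init, deparse.level = 0)
  w <- if (identical(cfg$readout, "recall")) {
    recall_batch(M, Q, stop_threshold = 1e-4, max_iter = 300)$winner
  } else {
    apply(.rekam_response(M, Q), 2L, which.max)
  }
  tags <- dataset$list_tags[w]
  c(list1_pct = 100 * mean(tags == 1L), list2_pct = 100 * mean(tags == 2L))
}

#' Run the list-learning simulation
#'
#' Runs the reminded group (A, configured by `cfg_A`) and the
#' no-reminder group (B, same configuration with no reconsolidation
#' updates unless `cfg_B` overrides it) on a shared stimulus set and
#' shared query noise, and reports the normalized per-list recall
#' percentages for each tested list (they sum to 100 within a group and
#' test by construction).
#'
#' @param cfg_A configuration of the reminded group.
#' @param cfg_B configuration of the control group; default: `cfg_A`
#'   without updates.
#' @param dataset optional pre-generated [gen_list_stimuli()] output.
#' @param test_lists which lists to test (default both).
#' @return an object of class `"list_learning_report"`: list with
#'   `table` (group x test percentages), `sigma_v` actually used, and
#'   the configurations.
#' @export
run_list_learning <- function(cfg_A, cfg_B = NULL, dataset = NULL,
                              test_lists = 1:2) {
  stopifnot(inherits(cfg_A, "list_learning_config"))
  if (is.null(cfg_B)) cfg_B <- cfg_A
  if (is.null(dataset)) dataset <- gen_list_stimuli(cfg_A)
  qn <- .list_query_noise(dataset)
  M_A <- .list_memory(dataset, cfg_A, reminded = TRUE)
  M_B <- .list_memory(dataset, cfg_B, reminded = FALSE)
  rows <- list()
  for (tl in test_lists) {
    rows[[length(rows) + 1L]] <-
      data.frame(group = "A", test_list = tl, t(.list_test(M_A, dataset, cfg_A, qn, tl)))
    rows[[length(rows) + 1L]] <-
      data.frame(group = "B", test_list = tl, t(.list_test(M_B, dataset, cfg_B, qn, tl)))
  }
  structure(list(table = do.call(rbind, rows),
                 sigma_v = if (is.null(cfg_A$sigma_v))
                   median_bandwidth(dataset$images) else cfg_A$sigma_v,
                 cfg_A = cfg_A, cfg_B = cfg_B),
            class = "list_learning_report")
}

#' @export
print.list_learning_report <- function(x, ...) {
  cat("List-learning simulation (normalized recall percentages)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Sweep the reconsolidation step of the reminded group
#'
#' Reruns the group-A protocol over a grid of indicator-shift steps
#' \eqn{\varepsilon} with common random numbers, tracing how List-2
#' intrusions into the List-1 test grow with the strength of
#' reconsolidation (the family of outcomes between the no-update control
#' and full merging).
#'
#' @param cfg a [list_learning_config()] (its `shift_step` is ignored).
#' @param eps_values vector of steps to evaluate.
#' @param dataset optional shared [gen_list_stimuli()] output.
#' @param test_list tested list (default 1).
#' @return data frame with columns `eps`, `list1_pct`, `list2_pct`.
#' @export
run_list_sweep <- function(cfg, eps_values, dataset = NULL, test_list = 1) {
  if (is.null(dataset)) dataset <- gen_list_stimuli(cfg)
  qn <- .list_query_noise(dataset)
  out <- lapply(eps_values, function(eps) {
    cfg_e <- cfg; cfg_e$shift_step <- eps
    p <- .list_test(.list_memory(dataset, cfg_e, reminded = eps > 0),
                    dataset, cfg_e, qn, test_list)
    data.frame(eps = eps, list1_pct = p[["list1_pct"]], list2_pct = p[["list2_pct"]])
  })
  do.call(rbind, out)
}

#' Calibrate the list-learning simulation against group percentages
#'
#' The kernel balance (\eqn{\sigma_v}, \eqn{\sigma_r}), the query
#' indicator `r_init` and the reminded-event step \eqn{\varepsilon} are
#' free parameters of the simulation.  This routine performs the
#' documented two-stage grid sweep: stage 1 selects the kernel balance
#' and `r_init` whose \emph{control-group} List-1 percentage best
#' matches `target_B`; stage 2, with those fixed, sweeps \eqn{\varepsilon}
#' (coarse grid plus local refinement) to match the reminded group's
#' List-1 percentage to `target_A`.  All sweep points share the stimulus
#' set and query noise (common random numbers).
#'
#' @param cfg base [list_learning_config()].
#' @param target_A,target_B normalized List-1 percentages to match for
#'   the reminded and control group (defaults: the human list-learning
#'   group values 60.399 and 90.180).
#' @param sigma_v_factors stage-1 grid of \eqn{\sigma_v} as multiples
#'   of the median pairwise image distance.
#' @param r_init_grid stage-1 grid of query indicator values.
#' @param sigma_r_grid stage-1 grid of indicator bandwidths.
#' @param eps_grid stage-2 coarse grid of reconsolidation steps.
#' @param refine_eps half-width of the stage-2 local refinement
#'   (step 0.01); 0 disables refinement.
#' @param keep_candidates how many near-best stage-1 candidates carry
#'   into stage 2 (default 12; the control group's percentage often plateaus, so
#'   the reminded-group sweep disambiguates between them).
#' @return an object of class `"list_calibration"`: the selected
#'   parameters, the achieved `pct_A` and `pct_B`, and both sweep
#'   tables.
#' @export
calibrate_list_learning <- function(cfg = list_learning_config(),
                                    target_A = 60.399, target_B = 90.180,
                                    sigma_v_factors = seq(0.75, 1.10, by = 0.025),
                                    r_init_grid = c(0.33, 0.35, 0.37, 0.39, 0.41),
                                    sigma_r_grid = 1.1,
                                    eps_grid = seq(0.05, 0.95, by = 0.05),
                                    refine_eps = 0.04,
                                    keep_candidates = 12L) {
  dataset <- gen_list_stimuli(cfg)
  qn <- .list_query_noise(dataset)
  med <- median_bandwidth(dataset$images)

  ## stage 1: control group over the kernel balance and query indicator
  grid_B <- expand.grid(sigma_v = med * sigma_v_factors,
                        sigma_r = sigma_r_grid, r_init = r_init_grid)
  grid_B$list1_pct <- NA_real_
  for (sr in sigma_r_grid) for (sv in unique(grid_B$sigma_v)) {
    cfg_k <- cfg; cfg_k$sigma_v <- sv; cfg_k$sigma_r <- sr
    M_B <- .list_memory(dataset, cfg_k, reminded = FALSE)
    for (ri in r_init_grid) {
      cfg_q <- cfg_k; cfg_q$r_init <- ri
      sel <- grid_B$sigma_v == sv & grid_B$sigma_r == sr & grid_B$r_init == ri
      grid_B$list1_pct[sel] <- .list_test(M_B, dataset, cfg_q, qn, 1L)[["list1_pct"]]
    }
  }
  grid_B$dev <- abs(grid_B$list1_pct - target_B)
  ## the control percentage plateaus in sigma_v; per (sigma_r, r_init)
  ## keep the flattest data kernel still matching it (largest sigma_v),
  ## which gives the reminded-group sweep its widest dynamic range
  near <- grid_B[grid_B$dev <= min(grid_B$dev) + 1.0, , drop = FALSE]
  keys <- interaction(near$sigma_r, near$r_init, drop = TRUE)
  cand <- do.call(rbind, lapply(split(near, keys), function(d)
    d[which.max(d$sigma_v), , drop = FALSE]))
  cand <- cand[order(cand$dev), , drop = FALSE]
  cand <- utils::head(cand, keep_candidates)

  ## stage 2: reminded group's step swept for each surviving candidate;
  ## final pick minimizes the joint deviation from both group targets
  best <- NULL
  for (ci in seq_len(nrow(cand))) {
    cfg_c <- cfg
    cfg_c$sigma_v <- cand$sigma_v[ci]
    cfg_c$sigma_r <- cand$sigma_r[ci]
    cfg_c$r_init <- cand$r_init[ci]
    gA <- run_list_sweep(cfg_c, eps_grid, dataset = dataset)
    e0 <- gA$eps[which.min(abs(gA$list1_pct - target_A))]
    if (refine_eps > 0) {
      fine <- seq(max(0, e0 - refine_eps), min(1, e0 + refine_eps), by = 0.01)
      fine <- setdiff(round(fine, 10), round(gA$eps, 10))
      if (length(fine)) gA <- rbind(gA, run_list_sweep(cfg_c, fine, dataset = dataset))
      gA <- gA[order(gA$eps), ]
    }
    k <- which.min(abs(gA$list1_pct - target_A))
    score <- abs(gA$list1_pct[k] - target_A) + cand$dev[ci]
    if (is.null(best) || score < best$score) {
      best <- list(score = score, cfg = cfg_c, eps = gA$eps[k],
                   pct_A = gA$list1_pct[k], pct_B = cand$list1_pct[ci],
                   grid_A = gA)
    }
  }
  cfg_cal <- best$cfg
  cfg_cal$shift_step <- best$eps
  structure(list(sigma_v = cfg_cal$sigma_v, sigma_r = cfg_cal$sigma_r,
                 r_init = cfg_cal$r_init, eps = best$eps,
                 pct_A = best$pct_A, pct_B = best$pct_B,
                 target_A = target_A, target_B = target_B,
                 grid_A = best$grid_A, grid_B = grid_B, cfg = cfg_cal),
            class = "list_calibration")
}

#' @export
print.list_calibration <- function(x, ...) {
  cat("List-learning calibration\n")
  cat(sprintf("  sigma_v = %.3f, sigma_r = %.3f, r_init = %.2f, eps = %.2f\n",
              x$sigma_v, x$sigma_r, x$r_init, x$eps))
  cat(sprintf("  group A List-1 %%: %.2f (target %.3f)\n", x$pct_A, x$target_A))
  cat(sprintf("  group B List-1 %%: %.2f (target %.3f)\n", x$pct_B, x$target_B))
  invisible(x)
}

## ---- extinction -----------------------------------------------------------

#' Configuration of the extinction simulation
#'
#' A Gaussian-kernel memory stores `n_images` synthetic images, one of
#' which (chosen at random) is the "shock" memory.  Its
#' attraction-radius scale is walked down `schedule`; at each value the
#' shock-retrieval frequency is estimated on `n_queries` random probes
#' uniform over the data bounding box.  The whole procedure repeats
#' `repeats` times with fresh images to attach a dispersion to each
#' point.
#'
#' The default schedule is dense near \eqn{\lambda = 1} and sparse
#' below: probes drawn uniformly over the bounding box sit at
#' comparable distances from every stored image, so the shock basin
#' loses its probe mass over a narrow band of scale reductions before
#' the long tail down to \eqn{\lambda = 10^{-3}} confirms complete
#' extinction.  Images are generated with light smoothing
#' (`smooth = 1`), which keeps their effective dimension high and the
#' stored set exchangeable (baseline retrieval close to `1/n_images`).
#'
#' @param n_images stored images (default 10).
#' @param image_dim pixels per image (perfect square).
#' @param schedule decreasing vector of scale values.
#' @param n_queries probes per schedule point (default 1000).
#' @param repeats independent repetitions (default 10).
#' @param smooth image smoothing half-width (see [gen_smooth_images()]).
#' @param readout retrieval readout, see [extinguish()].
#' @param seed RNG seed.
#' @export
extinction_config <- function(n_images = 10, image_dim = 256,
                              schedule = c(1, 0.995, 0.99, 0.98, 0.97, 0.96,
                                           0.95, 0.94, 0.92, 0.90, 0.87, 0.84,
                                           0.80, 0.75, 0.70, 0.60, 0.45, 0.30,
                                           0.15, 0.05, 0.01, 0.001),
                              n_queries = 1000, repeats = 10, smooth = 1,
                              readout = "response", seed = 1) {
  structure(list(n_images = n_images, image_dim = image_dim,
                 schedule = schedule, n_queries = n_queries,
                 repeats = repeats, smooth = smooth, readout = readout,
                 seed = seed),
            class = "extinction_config")
}

#' Run the extinction simulation
#'
#' @param cfg an [extinction_config()].
#' @return an object of class `"extinction_report"`: `curve` (data
#'   frame: `lambda`, `mean`, `sd` of the shock-retrieval frequency
#'   across repeats), `runs` (frequency matrix, one column per repeat),
#'   `other_mean` (mean total retrieval of the non-shock attractors at
#'   each point), and `cfg`.
#' @export
run_extinction <- function(cfg = extinction_config()) {
  stopifnot(inherits(cfg, "extinction_config"))
  set.seed(cfg$seed)
  runs <- matrix(NA_real_, length(cfg$schedule), cfg$repeats)
  other <- matrix(NA_real_, length(cfg$schedule), cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    images <- gen_smooth_images(cfg$n_images, cfg$image_dim, smooth = cfg$smooth)
    shock <- sample.int(cfg$n_images, 1L)
    M <- rekam(images)
    ext <- extinguish(M, shock, cfg$schedule, n_queries = cfg$n_queries,
                      readout = cfg$readout)
    runs[, r] <- ext$curve$frequency
    other[, r] <- 1 - ext$curve$frequency
  }
  structure(list(curve = data.frame(lambda = cfg$schedule,
                                    mean = rowMeans(runs),
                                    sd = apply(runs, 1L, stats::sd)),
                 runs = runs, other_mean = rowMeans(other), cfg = cfg),
            class = "extinction_report")
}

#' @export
print.extinction_report <- function(x, ...) {
  cat("Extinction simulation: shock-retrieval frequency vs basin scale\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.extinction_report <- function(x, ...) {
  graphics::plot(x$curve$lambda, x$curve$mean, log = "x", type = "b",
                 xlab = expression(lambda[shock]),
                 ylab = "retrieval frequency",
                 main = "extinction of the shock memory", ...)
  graphics::arrows(x$curve$lambda, pmax(0, x$curve$mean - x$curve$sd),
                   x$curve$lambda, x$curve$mean + x$curve$sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

## ---- rotation tracking ----------------------------------------------------

#' Run the rotating-glyph tracking experiment
#'
#' Loads the angle-0 glyphs (one attractor per exemplar, labeled by
#' class) into a weighted-Gaussian-kernel memory after
#' principal-component preprocessing, then presents the rotated stimuli
#' in increasing angle order (or shuffled, if configured).  Each
#' stimulus is recalled — its classification is the winning attractor's
#' class — and, depending on `cfg$mode`, the memory is reconsolidated
#' toward it with the approximate (local) update, the exact geodesic
#' update, or not at all.
#'
#' @param cfg a [rotation_config()].
#' @param glyphs optional pre-generated [gen_rotating_glyphs()] output
#'   (shared across modes for paired comparisons).
#' @param exact_opts optimizer options for the exact mode.  The
#'   default is a deliberately coarse budget (30 BFGS iterations with a
#'   strong chart penalty), in the spirit of the coarse derivative-free
#'   optimization such geodesic trackers run per event; see the methods
#'   vignette for the exact-vs-approximate comparison this implies.
#' @param recall_args arguments passed to [recall()] for every
#'   presentation (the feature-space recall map has a slow relaxation
#'   tail, so the default allows up to 1000 iterations at a `1e-5`
#'   stop threshold).
#' @return an object of class `"tracking_report"`: `accuracy` (data
#'   frame: `angle`, `accuracy`, `n`), `overall` accuracy,
#'   `confusion_final` (table at the largest angle), `presentations`
#'   (one row per stimulus), `final_attractors`, `pca_k`, and `cfg`.
#' @export
run_tracking <- function(cfg = rotation_config(), glyphs = NULL,
                         exact_opts = list(maxit = 30, reltol = 1e-8,
                                           chart_penalty = 0.1),
                         recall_args = list(stop_threshold = 1e-5,
                                            max_iter = 1000)) {
  stopifnot(inherits(cfg, "rotation_config"))
  if (is.null(glyphs)) glyphs <- gen_rotating_glyphs(cfg)
  pca <- pca_fit(glyphs$images, cfg$pca_variance_target)
  feats <- pca_apply(pca, glyphs$images)

  base_cols <- which(glyphs$info$step == 1L)
  base_cols <- base_cols[order(glyphs$info$exemplar[base_cols])]
  att <- feats[, base_cols, drop = FALSE]
  cls <- glyphs$info$class[base_cols]

  wts <- weights_inverse_sd(feats)
  dw <- sqrt(.wsqdist(att, att, wts))
  sv <- cfg$sigma_factor * stats::median(dw[upper.tri(dw)])
  ks <- kernel_spec("weighted_gaussian", sigma_v = sv, weights = wts)
  M <- rekam(att, kernel = ks, labels = cls)

  pres <- which(glyphs$info$step >= 2L)
  pres <- pres[order(glyphs$info$step[pres], glyphs$info$exemplar[pres])]
  if (cfg$shuffle) {
    set.seed(cfg$seed + 1L)
    pres <- sample(pres)
  }

  rows <- vector("list", length(pres))
  for (k in seq_along(pres)) {
    i <- pres[k]
    stim <- feats[, i]
    r <- do.call(recall, c(list(M, stim), recall_args))
    wcls <- M$labels[r$winner]
    rows[[k]] <- data.frame(order = k, angle = glyphs$info$angle[i],
                            class = glyphs$info$class[i],
                            exemplar = glyphs$info$exemplar[i],
                            winner = r$winner, winner_class = wcls,
                            correct = wcls == glyphs$info$class[i],
                            converged = r$converged)
    if (cfg$mode != "none") {
      M <- reconsolidate(M, stim, step = cfg$shift_step,
                         mode = if (cfg$mode == "exact") "exact_geodesic"
                                else "approximate",
                         opts = exact_opts, recall_args = recall_args)
    }
  }
  pr <- do.call(rbind, rows)
  acc <- stats::aggregate(correct ~ angle, data = pr, FUN = mean)
  names(acc) <- c("angle", "accuracy")
  acc$n <- stats::aggregate(correct ~ angle, data = pr, FUN = length)$correct
  amax <- max(pr$angle)
  fin <- pr[pr$angle == amax, ]
  structure(list(accuracy = acc, overall = mean(pr$correct),
                 confusion_final = table(true = fin$class,
                                         predicted = fin$winner_class),
                 presentations = pr, final_attractors = M$attractors,
                 journal = M$journal, pca_k = pca$k, cfg = cfg),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("Rotation tracking (%s mode%s): overall accuracy %.1f%%\n",
              x$cfg$mode, if (x$cfg$shuffle) ", shuffled order" else "",
              100 * x$overall))
  amax <- max(x$accuracy$angle)
  cat(sprintf("  accuracy at largest angle (%g deg): %.1f%%\n", amax,
              100 * x$accuracy$accuracy[x$accuracy$angle == amax]))
  cat(sprintf("  PCA components: %d\n", x$pca_k))
  invisible(x)
}

#' @export
plot.tracking_report <- function(x, ...) {
  graphics::plot(x$accuracy$angle, 100 * x$accuracy$accuracy, type = "l",
                 ylim = c(0, 100), xlab = "rotation angle (deg)",
                 ylab = "classification accuracy (%)",
                 main = sprintf("tracking under %s reconsolidation", x$cfg$mode),
                 ...)
  invisible(x)
}
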