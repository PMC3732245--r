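test_that("list-learning stimuli are sized, bounded and reproducible", {
  cfg <- list_learning_config(seed = 5)
  d1 <- gen_list_stimuli(cfg)
  expect_equal(ncol(d1$patterns), 40L)
  expect_equal(nrow(d1$patterns), cfg$image_dim + 1L)
  expect_true(all(abs(d1$images) <= 1))
  expect_equal(d1$patterns[cfg$image_dim + 1L, ], rep(c(1, 0), each = 20))

  d2 <- gen_list_stimuli(cfg)
  expect_identical(d1$patterns, d2$patterns)          # same seed, bit-identical
  d3 <- gen_list_stimuli(list_learning_config(seed = 6))
  expect_false(identical(d1$patterns, d3$patterns))

  ## pairwise distances concentrated enough for comparable basins
  D <- as.matrix(dist(t(d1$images)))
  dd <- D[upper.tri(D)]
  expect_lt(sd(dd) / mean(dd), 0.5)
})

test_that("without updates the two groups are indistinguishable", {
  cfg <- list_learning_config(queries_per_list = 300, shift_step = 0)
  rep <- run_list_learning(cfg)
  tab <- rep$table
  a1 <- tab[tab$group == "A" & tab$test_list == 1, "list1_pct"]
  b1 <- tab[tab$group == "B" & tab$test_list == 1, "list1_pct"]
  expect_equal(a1, b1)                               # common random numbers
  ## normalization: per group and test the two percentages sum to 100
  expect_equal(tab$list1_pct + tab$list2_pct, rep(100, nrow(tab)), tolerance = 1e-9)
})

test_that("List-2 intrusions grow monotonically with the reminded step", {
  cfg <- list_learning_config(queries_per_list = 400, r_init = 0.37)
  cfg$sigma_v <- 0.95 * median_bandwidth(gen_list_stimuli(cfg)$images)
  sweep <- run_list_sweep(cfg, eps_values = seq(0, cfg$r_init, by = 0.05))
  expect_true(all(diff(sweep$list2_pct) >= -1e-9))
  expect_lt(sweep$list1_pct[nrow(sweep)], sweep$list1_pct[1])
})

test_that("the extinction report conserves retrieval and is reproducible", {
  cfg <- extinction_config(repeats = 2, n_queries = 200,
                           schedule = c(1, 0.95, 0.9, 0.7, 0.3, 0.001))
  r1 <- run_extinction(cfg)
  expect_equal(r1$curve$lambda, cfg$schedule)
  expect_true(all(diff(r1$curve$mean) <= 1e-12))
  expect_equal(r1$other_mean, 1 - r1$curve$mean, tolerance = 1e-12)
  r2 <- run_extinction(cfg)
  expect_identical(r1$runs, r2$runs)
})

test_that("glyph generation and rotation behave geometrically", {
  cfg <- rotation_config(n_classes = 3, per_class = 2, n_steps = 4,
                         angle_step = 30, seed = 3)
  g <- gen_rotating_glyphs(cfg)
  expect_equal(ncol(g$images), 3 * 2 * 4)
  expect_equal(nrow(g$images), cfg$image_size^2)
  ## angle-0 stimuli are the unrotated bases
  expect_equal(g$images[, g$info$angle == 0], g$base)

  ## same seed -> bit-identical; the info table is aligned
  g2 <- gen_rotating_glyphs(cfg)
  expect_identical(g$images, g2$images)
  expect_equal(nrow(g$info), ncol(g$images))

  ## a point-symmetric glyph (the plus prototype) survives 180 degrees
  plus <- rekam:::.render_glyph(rekam:::.glyph_strokes(6), 24, 0.05)
  expect_lt(mean(abs(rotate_image(plus, 180) - plus)), 0.02)

  ## rotate theta then -theta returns the original up to interpolation blur
  img <- rekam:::.render_glyph(rekam:::.glyph_strokes(1), 24, 0.05)
  back <- rotate_image(rotate_image(img, 35), -35)
  interior <- matrix(FALSE, 24, 24); interior[5:20, 5:20] <- TRUE
  expect_lt(mean(abs(back - img)[interior]), 0.05)
})

test_that("PCA preprocessing picks the smallest sufficient component count", {
  set.seed(4)
  ## full-rank data at target 1.0 keeps min(n, samples - 1) components
  D <- matrix(rnorm(10 * 30), 10, 30)
  expect_equal(pca_fit(D, 1.0)$k, 10L)

  ## data confined to an exact 3-dimensional subspace
  B <- matrix(rnorm(10 * 3), 10, 3)
  D3 <- B %*% matrix(rnorm(3 * 40), 3, 40)
  p3 <- pca_fit(D3, 0.99)
  expect_equal(p3$k, 3L)

  ## reconstruction error equals the discarded eigenvalue mass
  p <- pca_fit(D, 0.6)
  Z <- pca_apply(p, D)
  recon <- p$rotation %*% Z + p$center
  sse <- sum((D - recon)^2)
  ev <- prcomp(t(D))$sdev^2
  expect_equal(sse / (ncol(D) - 1), sum(ev[(p$k + 1):length(ev)]), tolerance = 1e-8)

  expect_error(pca_fit(D, 0), "variance_target")
  expect_error(pca_fit(D, 1.5), "variance_target")
})

test_that("a small tracking run is reproducible and starts accurate", {
  cfg <- rotation_config(n_classes = 3, per_class = 2, n_steps = 5,
                         angle_step = 6, mode = "approximate", seed = 7)
  r1 <- run_tracking(cfg)
  r2 <- run_tracking(cfg)
  expect_identical(r1$presentations, r2$presentations)
  expect_s3_class(r1$accuracy, "data.frame")
  ## small rotations right after loading stay on the correct exemplars
  first_angle <- min(r1$presentations$angle)
  expect_gte(mean(r1$presentations$correct[r1$presentations$angle == first_angle]),
             0.8)
  ## with reconsolidation the attractors must have moved
  expect_gt(norm(r1$final_attractors -
                 run_tracking(within_mode_none <- {
                   c0 <- cfg; c0$mode <- "none"; c0
                 })$final_attractors, "F"), 0.1)
})
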