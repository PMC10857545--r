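# numerical gradient check for the hand-derived backprop
grad_check <- function(config, n = 14, m = 2, seed = 99, tol = 1e-4) {
  set.seed(seed)
  X <- matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
  Target <- matrix(abs(rnorm(n * m)), n, m)
  if (config$sigmoid_head) Target <- Target / max(Target)
  p <- cowmorph:::.net_init(config, m)
  # jitter every parameter: zero-initialized biases otherwise leave some
  # pre-activations exactly on the ReLU kink, where a subgradient and a
  # finite difference legitimately disagree
  fp0 <- cowmorph:::.flatten(p)
  for (nm in names(fp0)) fp0[[nm]] <- fp0[[nm]] + rnorm(length(fp0[[nm]]), sd = 0.05)
  p <- cowmorph:::.apply_flat(p, fp0)
  loss_at <- function(pp) {
    mean((cowmorph:::.net_forward(pp, config, X)$Y - Target)^2)
  }
  fw <- cowmorph:::.net_forward(p, config, X)
  g <- cowmorph:::.net_backward(p, config, fw$cache, Target)
  fp <- cowmorph:::.flatten(p)
  fg <- cowmorph:::.flatten(g)
  set.seed(seed + 1)
  for (nm in names(fp)) {
    # probe a handful of random entries per parameter block
    for (k in sample(length(fp[[nm]]), min(3, length(fp[[nm]])))) {
      eps <- 1e-5
      pp <- fp
      pp[[nm]][k] <- pp[[nm]][k] + eps
      up <- loss_at(cowmorph:::.apply_flat(p, pp))
      pp[[nm]][k] <- pp[[nm]][k] - 2 * eps
      dn <- loss_at(cowmorph:::.apply_flat(p, pp))
      num <- (up - dn) / (2 * eps)
      ana <- fg[[nm]][k]
      rel <- abs(ana - num) / max(1e-3, abs(num), abs(ana))
      expect_lt(rel, tol, label = sprintf("grad %s[%d] mismatch %.2e", nm, k, rel))
    }
  }
}

test_that("backprop matches finite differences for every head and T-Net", {
  base <- list(encoder_widths = c(5, 6, 7), decoder_widths = c(6, 5),
               sample_points = NULL)
  grad_check(do.call(pointnet_config, c(base, head = "norm")))
  grad_check(do.call(pointnet_config, c(base, head = "linear")))
  grad_check(do.call(pointnet_config, c(base, sigmoid_head = TRUE)))
  grad_check(do.call(pointnet_config, c(base, head = "norm",
                                        use_input_tnet = TRUE,
                                        use_feature_tnet = TRUE)))
})

test_that("the configuration guards its contract", {
  expect_error(pointnet_config(learning_rate = 0), "positive")
  expect_error(pointnet_config(epochs = 0), "at least 1")
  expect_error(pointnet_config(loss = "mae"), "mean-squared-error")
  expect_error(pointnet_config(optimizer = "sgd"), "Adam")
  expect_error(pointnet_config(encoder_widths = 8), "two encoder layers")
})

make_tiny_dataset <- function(n_scenes = 1, n = 90, seed = 71) {
  lapply(seq_len(n_scenes), function(i) {
    pc <- rand_cloud(n, seed = seed + i, scale = 0.4)
    idx <- c(4L, 40L)
    list(cloud = pc,
         annotation = keypoint_set(c("a", "b"),
                                   pc$points[idx, , drop = FALSE],
                                   index = idx))
  })
}

test_that("a tiny scene is overfit by two orders of magnitude", {
  ds <- make_tiny_dataset()
  cfg <- pointnet_config(encoder_widths = c(16, 16, 32),
                         decoder_widths = c(32, 16), epochs = 250,
                         lr_decay = "none", sample_points = NULL, seed = 7)
  fit <- fit_keypoint_model(ds, cfg)
  expect_gte(fit$loss[1] / fit$loss[length(fit$loss)], 100)
})

test_that("prediction is shape-correct, non-negative and deterministic", {
  ds <- make_tiny_dataset()
  cfg <- pointnet_config(encoder_widths = c(8, 8, 12), decoder_widths = c(12, 8),
                         epochs = 5, sample_points = NULL, seed = 3)
  fit <- fit_keypoint_model(ds, cfg)
  pc <- rand_cloud(37, seed = 81)
  f1 <- predict(fit, pc)
  expect_equal(dim(f1), c(37L, 2L))
  expect_true(all(f1 >= 0))
  expect_identical(f1, predict(fit, pc))
  expect_error(predict(fit, point_cloud(matrix(numeric(0), ncol = 3))), "empty")
})

test_that("permuting the input points permutes the field rows identically", {
  ds <- make_tiny_dataset()
  cfg <- pointnet_config(encoder_widths = c(8, 8, 12), decoder_widths = c(12, 8),
                         epochs = 5, sample_points = NULL, seed = 3)
  fit <- fit_keypoint_model(ds, cfg)
  pc <- rand_cloud(40, seed = 82)
  set.seed(83)
  perm <- sample(40)
  f_perm <- predict(fit, subset_cloud(pc, perm))
  f_base <- predict(fit, pc)
  expect_equal(f_perm, f_base[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("checkpoints round-trip weights, names and config", {
  ds <- make_tiny_dataset()
  cfg <- pointnet_config(encoder_widths = c(8, 8, 12), decoder_widths = c(12, 8),
                         epochs = 4, use_input_tnet = TRUE, seed = 5,
                         sample_points = NULL)
  fit <- fit_keypoint_model(ds, cfg)
  f <- withr::local_tempfile(fileext = ".bin")
  save_keypoint_model(fit, f)
  back <- load_keypoint_model(f)
  expect_equal(back$names, fit$names)
  expect_equal(back$config$encoder_widths, cfg$encoder_widths)
  expect_true(back$config$use_input_tnet)
  pc <- rand_cloud(25, seed = 84)
  expect_identical(predict(back, pc), predict(fit, pc))
  writeLines("junk", f)
  expect_error(load_keypoint_model(f))
})

test_that("training refuses inconsistent keypoint sets", {
  ds <- make_tiny_dataset(2)
  ds[[2]]$annotation$names <- c("a", "zzz")
  expect_error(fit_keypoint_model(ds), "same ordered keypoint names")
  expect_error(fit_keypoint_model(list()), "at least one scene")
})

test_that("held-out localization degrades with sensor noise", {
  run_at_noise <- function(sigma) {
    rng <- default_template_ranges()
    rng$noise_sigma <- c(sigma, sigma)
    rng$points_per_scene <- c(3000, 3000)
    scenes <- generate_training_set(16, rng, seed = 501)
    prep <- lapply(seq_along(scenes), function(i)
      prepare_keypoint_scene(scenes[[i]], max_points = 1e9, seed = 600 + i))
    tr <- c(prep[1:12], lapply(prep[1:12], mirror_prepared_scene))
    cfg <- pointnet_config(epochs = 40, sample_points = 256, seed = 11)
    fit <- fit_keypoint_model(tr, cfg)
    attr(evaluate_keypoint_model(fit, prep[13:16]), "median")
  }
  errs <- vapply(c(0.001, 0.008, 0.025), run_at_noise, numeric(1))
  expect_lt(errs[1], errs[3])
})

test_that("mirroring a prepared scene swaps the paired landmarks exactly", {
  sc <- small_scene(seed = 91, n = 3000)
  ps <- prepare_keypoint_scene(sc, max_points = 500, seed = 92)
  mir <- mirror_prepared_scene(ps)
  expect_equal(unname(kp(mir$truth_keypoints, "hook_A1")),
               unname(kp(ps$truth_keypoints, "aux_B1")) * c(1, -1, 1))
  expect_equal(unname(kp(mir$truth_keypoints, "teat_left_top")),
               unname(kp(ps$truth_keypoints, "teat_right_top")) * c(1, -1, 1))
  # mirrored annotation still indexes members of the mirrored cloud
  expect_equal(unname(mir$cloud$points[mir$annotation$index, , drop = FALSE]),
               unname(mir$annotation$points))
})
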