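test_that("evaluation of a perfect and a hopeless alignment", {
  pc <- rand_cloud(300, seed = 31, scale = 0.01)
  res <- evaluate_registration(pc, pc, max_corr_dist = 0.03)
  expect_equal(res$fitness, 1)
  expect_equal(res$inlier_rmse, 0)
  far <- apply_transform(pc, rigid_transform_rt(diag(3), c(0.3, 0, 0)))
  res2 <- evaluate_registration(far, pc, max_corr_dist = 0.03)
  expect_equal(res2$fitness, 0)
  expect_equal(res2$correspondence_count, 0L)
  expect_error(evaluate_registration(point_cloud(matrix(numeric(0), ncol = 3)), pc),
               "non-empty")
})

test_that("evaluation equals the exhaustive nearest-neighbour oracle", {
  src <- rand_cloud(120, seed = 32)
  tgt <- rand_cloud(90, seed = 33)
  mcd <- 0.5
  res <- evaluate_registration(src, tgt, mcd)
  D <- outer(rowSums(src$points^2), rowSums(tgt$points^2), `+`) -
    2 * src$points %*% t(tgt$points)
  nn <- sqrt(pmax(apply(D, 1, min), 0))
  inl <- nn <= mcd
  expect_equal(res$fitness, mean(inl))
  expect_equal(res$correspondence_count, sum(inl))
  expect_equal(res$inlier_rmse, sqrt(mean(nn[inl]^2)), tolerance = 1e-12)
})

test_that("evaluation is invariant under a common rigid motion", {
  src <- rand_cloud(150, seed = 35)
  tgt <- rand_cloud(150, seed = 36)
  base <- evaluate_registration(src, tgt, 0.4)
  M <- rand_rigid(seed = 37)
  moved <- evaluate_registration(apply_transform(src, M), apply_transform(tgt, M), 0.4)
  expect_equal(moved$fitness, base$fitness)
  expect_equal(moved$inlier_rmse, base$inlier_rmse, tolerance = 1e-9)
})

test_that("fitness is non-increasing as the correspondence distance shrinks", {
  src <- rand_cloud(200, seed = 38)
  tgt <- rand_cloud(200, seed = 39)
  fits <- sapply(c(1, 0.5, 0.2, 0.1, 0.05), function(d)
    evaluate_registration(src, tgt, d)$fitness)
  expect_true(all(diff(fits) <= 0))
})

test_that("ICP recovers a known small rigid perturbation", {
  sc <- small_scene(seed = 41, noise = 0, outliers = 0)
  tgt <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  perturb <- rand_rigid(seed = 42, max_angle = 4 * pi / 180, max_trans = 0.015)
  src <- apply_transform(tgt, perturb)
  est <- icp_point_to_point(src, tgt, max_corr_dist = 0.08, max_iter = 60,
                            tol = 1e-10)
  resid <- transform_compose(est, perturb)  # should be the identity
  expect_lt(rotation_angle(resid$matrix[1:3, 1:3]), 1e-3)
  expect_lt(sqrt(sum(resid$matrix[1:3, 4]^2)), 1e-3)
})

test_that("ICP started at the exact answer stays there", {
  sc <- small_scene(seed = 43, noise = 0, outliers = 0)
  tgt <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  perturb <- rand_rigid(seed = 44, max_angle = 3 * pi / 180, max_trans = 0.01)
  src <- apply_transform(tgt, perturb)
  exact <- transform_inverse(perturb)
  est <- icp_point_to_point(src, tgt, init = exact, max_corr_dist = 0.05,
                            max_iter = 10)
  expect_equal(est$matrix, exact$matrix, tolerance = 1e-9)
})

test_that("ICP reduces the alignment RMSE relative to its start", {
  sc <- small_scene(seed = 45, noise = 0.003, outliers = 0)
  tgt <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  perturb <- rand_rigid(seed = 46, max_angle = 4 * pi / 180, max_trans = 0.02)
  src <- apply_transform(tgt, perturb)
  before <- evaluate_registration(src, tgt, 0.08)$inlier_rmse
  est <- icp_point_to_point(src, tgt, max_corr_dist = 0.08, max_iter = 40)
  after <- evaluate_registration(src, tgt, 0.08, est)$inlier_rmse
  expect_lte(after, before + 1e-12)
  # and the per-iteration objective is non-increasing on this fixture
  rmses <- sapply(1:6, function(k)
    evaluate_registration(src, tgt, 0.08,
                          icp_point_to_point(src, tgt, max_corr_dist = 0.08,
                                             max_iter = k))$inlier_rmse)
  expect_true(all(diff(rmses) <= 1e-9))
})

test_that("ICP with no initial overlap raises a no-overlap error", {
  a <- rand_cloud(50, seed = 47)
  b <- apply_transform(a, rigid_transform_rt(diag(3), c(10, 0, 0)))
  expect_error(icp_point_to_point(a, b, max_corr_dist = 0.05), "overlap")
})

test_that("the fixed initialization improves the two-camera stitch", {
  sc <- small_scene(seed = 48, noise = 0, outliers = 0, n = 3000)
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  zmid <- median(body$points[, 3])
  bottom <- subset_cloud(body, body$points[, 3] < zmid + 0.08)
  top_true <- subset_cloud(body, body$points[, 3] > zmid - 0.08)
  # pre-displace the top cloud so the calibration transform re-aligns it
  top <- apply_transform(top_true, transform_inverse(initialization_matrix()))
  before <- evaluate_registration(top, bottom, 0.03)
  st <- stitch_with_initialization(top, bottom)
  expect_gt(st$result$fitness, before$fitness)
  expect_equal(n_points(st$cloud), n_points(top) + n_points(bottom))
  st_ref <- stitch_with_initialization(top, bottom, refine = TRUE)
  expect_lte(st_ref$result$inlier_rmse, st$result$inlier_rmse + 1e-12)
})
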