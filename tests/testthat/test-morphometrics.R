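test_that("score tables hold nine strictly increasing reference rows", {
  for (tr in c("stature", "rump_angle", "rump_width", "teat_length")) {
    tab <- score_table(tr)
    expect_equal(nrow(tab), 9)
    expect_equal(tab$score, 1:9)
    expect_true(all(diff(tab$value) > 0))
  }
  expect_equal(score_table("stature")$value, seq(128, 152, by = 3))
  expect_equal(score_table("rump_angle")$value, seq(-4, 12, by = 2))
  expect_equal(score_table("rump_width")$value, seq(5, 17, by = 1.5))
  expect_equal(score_table("teat_length")$value, 2:10)
})

test_that("the printed value-score pairs reproduce under the nearest-row rule", {
  expect_equal(score_measurement(142.0, "stature"), 6L)
  expect_equal(score_measurement(6.06, "rump_angle"), 6L)
  expect_equal(score_measurement(11.7, "rump_width"), 5L)
  expect_equal(score_measurement(4.16, "teat_length"), 3L)
  expect_equal(score_measurement(140, "stature"), 5L)
})

test_that("scores clamp at the extremes and midpoints round up", {
  expect_equal(score_measurement(120, "stature"), 1L)
  expect_equal(score_measurement(200, "stature"), 9L)
  expect_equal(score_measurement(141.5, "stature"), 6L)  # midpoint of 140/143
  expect_equal(score_measurement(c(128, 152), "stature"), c(1L, 9L))
})

test_that("scoring is a non-decreasing step map onto 1..9 for every trait", {
  for (tr in c("stature", "rump_angle", "rump_width", "teat_length")) {
    tab <- score_table(tr)
    grid <- seq(min(tab$value) - 5, max(tab$value) + 5, by = 0.01)
    s <- score_measurement(grid, tr)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= 1 & s <= 9))
  }
  expect_error(score_measurement(1, table = data.frame(a = 1)), "columns")
  expect_error(score_measurement(1, table = data.frame(value = c(2, 1), score = 1:2)),
               "increasing")
})

test_that("stature is the keypoint's distance to the ground plane in cm", {
  ks <- keypoint_set("highest_back", c(0.2, 0.1, 1.42))
  expect_equal(measure_stature(ks, plane(c(0, 0, 1), 0)), 142)
  expect_equal(measure_stature(keypoint_set("highest_back", c(1, 2, 0)),
                               plane(c(0, 0, 1), 0)), 0)
  # tilted-plane oracle via explicit projection
  set.seed(61)
  pl <- plane(rnorm(3), rnorm(1, sd = 0.2))
  x <- rnorm(3)
  foot <- x - (sum(pl$normal * x) + pl$offset) * pl$normal
  expect_equal(measure_stature(keypoint_set("highest_back", x), pl),
               100 * sqrt(sum((x - foot)^2)), tolerance = 1e-9)
  expect_error(measure_stature(keypoint_set("other", x), pl), "missing")
})

test_that("rump angle is the signed hook-minus-pin height difference", {
  gz <- plane(c(0, 0, 1), 0)
  level <- keypoint_set(c("hook_A1", "pin_A2"),
                        rbind(c(-0.4, 0.2, 1.25), c(-0.6, 0.1, 1.25)))
  expect_equal(measure_rump_angle(level, gz), 0)
  offs <- keypoint_set(c("hook_A1", "pin_A2"),
                       rbind(c(-0.4, 0.2, 1.30), c(-0.6, 0.1, 1.30 - 0.0606)))
  expect_equal(measure_rump_angle(offs, gz), 6.06, tolerance = 1e-9)
  # positive sign means the hook sits higher
  expect_gt(measure_rump_angle(offs, gz), 0)
  flipped <- keypoint_set(c("hook_A1", "pin_A2"),
                          rbind(c(-0.4, 0.2, 1.20), c(-0.6, 0.1, 1.26)))
  expect_lt(measure_rump_angle(flipped, gz), 0)
})

test_that("rump width uses the ischium pair inside the hook cross-section", {
  sc <- generate_scene(cow_template(noise_sigma = 0, outlier_fraction = 0,
                                    seed = 65))
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  w <- measure_rump_width(body, sc$truth$keypoints)
  expect_equal(w, sc$truth$measurements[["rump_width_cm"]], tolerance = 1e-9)
  # degenerate: identical ischium points measure zero
  ks <- sc$truth$keypoints
  ks$points["ischium_C2", ] <- ks$points["ischium_C1", ]
  expect_equal(measure_rump_width(body, ks), 0)
  # an empty slab is a geometry error
  far <- ks
  far$points["hook_A1", ] <- c(50, 0, 1)
  far$points["aux_B1", ] <- c(50, 1, 1)
  expect_error(measure_rump_width(body, far, slab_half_width = 1e-6), "empty slab")
})

test_that("without ischium keypoints the slab extrema provide the width", {
  # a synthetic slab: vertical plane x = 0 with known transverse extremes
  set.seed(66)
  slab <- cbind(runif(400, -0.01, 0.01), runif(400, -0.07, 0.07),
                runif(400, 0.70, 0.80))
  ks <- keypoint_set(c("hook_A1", "aux_B1"),
                     rbind(c(0, 0.3, 1.3), c(0, -0.3, 1.3)))
  w <- measure_rump_width(point_cloud(slab), ks, slab_half_width = 0.015)
  expect_equal(w, 100 * diff(range(slab[, 2])), tolerance = 2)
})

test_that("teat lengths average the labelled top-bottom distances", {
  ks <- keypoint_set(c("teat_left_top", "teat_left_bottom",
                       "teat_right_top", "teat_right_bottom"),
                     rbind(c(0.36, 0.06, 0.76), c(0.36, 0.06, 0.76 - 0.0406),
                           c(0.36, -0.06, 0.77), c(0.36, -0.06, 0.77 - 0.0426)))
  tl <- measure_teat_length(ks)
  expect_equal(unname(tl["left"]), 4.06, tolerance = 1e-9)
  expect_equal(unname(tl["right"]), 4.26, tolerance = 1e-9)
  expect_equal(unname(tl["avg"]), 4.16, tolerance = 1e-9)
  same <- keypoint_set(c("teat_left_top", "teat_left_bottom",
                         "teat_right_top", "teat_right_bottom"),
                       rbind(c(1, 1, 1), c(1, 1, 1), c(2, 2, 2), c(2, 2, 2)))
  expect_equal(unname(measure_teat_length(same)), c(0, 0, 0))
  expect_error(measure_teat_length(keypoint_set("teat_left_top", c(0, 0, 0))),
               "missing")
})

test_that("full reports keep the exact teat-average invariant and valid scores", {
  sc <- generate_scene(cow_template(noise_sigma = 0, outlier_fraction = 0,
                                    seed = 67))
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  rep <- measure_cow(body, sc$truth$keypoints, sc$truth$ground_plane)
  expect_identical(rep$teat_avg_cm, (rep$teat_left_cm + rep$teat_right_cm) / 2)
  expect_true(all(rep$scores >= 1 & rep$scores <= 9))
  expect_equal(rep$scores[["stature"]], 6L)
  expect_equal(rep$scores[["rump_angle"]], 6L)
  expect_equal(rep$scores[["rump_width"]], 5L)
  expect_equal(rep$scores[["teat_length"]], 3L)
})

test_that("report JSON round-trips to an equal report", {
  sc <- generate_scene(cow_template(noise_sigma = 0, outlier_fraction = 0,
                                    seed = 68))
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  rep <- measure_cow(body, sc$truth$keypoints, sc$truth$ground_plane)
  f <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, f)
  back <- report_from_json(f)
  for (field in c("stature_cm", "rump_angle_cm", "rump_width_cm",
                  "teat_left_cm", "teat_right_cm", "teat_avg_cm"))
    expect_equal(back[[field]], rep[[field]])
  expect_equal(back$scores, rep$scores)
})

test_that("annotation overlays are non-destructive and countable", {
  sc <- generate_scene(cow_template(noise_sigma = 0, outlier_fraction = 0,
                                    seed = 69, points_per_scene = 1200))
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  rep <- measure_cow(body, sc$truth$keypoints, sc$truth$ground_plane)
  out <- annotate_cloud(body, rep, sc$truth$keypoints)
  nm <- attr(out, "n_markers")
  expect_equal(n_points(out), n_points(body) + nm)
  expect_gte(nm, length(sc$truth$keypoints$names))
  # the original points pass through bit-identically
  expect_identical(unname(out$points[seq_len(n_points(body)), ]),
                   unname(body$points))
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(out, f)
  expect_equal(n_points(read_ply(f)), n_points(out))
})
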