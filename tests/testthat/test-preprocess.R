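test_that("voxel downsampling follows the centroid-per-voxel contract", {
  p1 <- point_cloud(matrix(c(0.31, 0.22, 0.13), 1))
  expect_equal(voxel_downsample(p1, 0.1)$points, p1$points)
  # two points in one voxel collapse to their midpoint
  p2 <- point_cloud(rbind(c(0.01, 0.01, 0.01), c(0.08, 0.05, 0.03)))
  expect_equal(voxel_downsample(p2, 0.1)$points,
               matrix(c(0.045, 0.03, 0.02), 1), ignore_attr = TRUE)
  # output count equals the number of distinct occupied voxels (hash oracle)
  set.seed(3)
  pc <- rand_cloud(10000, seed = 3, scale = 0.5)
  vs <- 0.07
  key <- apply(floor(pc$points / vs), 1, paste, collapse = "/")
  ds <- voxel_downsample(pc, vs)
  expect_equal(n_points(ds), length(unique(key)))
  expect_lte(n_points(ds), n_points(pc))
  # order independence
  perm <- sample(n_points(pc))
  ds2 <- voxel_downsample(subset_cloud(pc, perm), vs)
  o1 <- ds$points[order(ds$points[, 1], ds$points[, 2], ds$points[, 3]), ]
  o2 <- ds2$points[order(ds2$points[, 1], ds2$points[, 2], ds2$points[, 3]), ]
  expect_equal(o1, o2, tolerance = 1e-12)
  expect_error(voxel_downsample(pc, 0), "positive")
})

test_that("point-plane distance matches the explicit projection oracle", {
  gz <- plane(c(0, 0, 1), 0)
  expect_equal(point_plane_distance(c(0, 0, 1.42), gz), 1.42)
  expect_equal(point_plane_distance(c(3, -2, 0), gz), 0)
  set.seed(9)
  for (i in 1:20) {
    pl <- plane(rnorm(3), rnorm(1))
    x <- rnorm(3, sd = 2)
    # orthogonal projection foot, then Euclidean distance to it
    foot <- x - (sum(pl$normal * x) + pl$offset) * pl$normal
    expect_equal(point_plane_distance(x, pl), sqrt(sum((x - foot)^2)),
                 tolerance = 1e-12)
  }
})

test_that("RANSAC recovers an exact dominant plane", {
  set.seed(4)
  on_plane <- cbind(runif(100, -1, 1), runif(100, -1, 1), 0)
  far <- cbind(runif(5), runif(5), runif(5, 2, 3))
  fit <- fit_plane_ransac(point_cloud(rbind(on_plane, far)),
                          dist_thresh = 0.01, n_iters = 200, seed = 1)
  expect_equal(abs(fit$plane$normal[3]), 1, tolerance = 1e-9)
  expect_equal(fit$plane$offset, 0, tolerance = 1e-9)
  expect_equal(length(fit$inliers), 100)
})

test_that("RANSAC on a noiseless scene recovers the ground exactly", {
  sc <- small_scene(seed = 6, noise = 0, outliers = 0)
  fit <- fit_plane_ransac(sc$cloud, 0.015, 1000, seed = 2)
  n <- fit$plane$normal * sign(fit$plane$normal[3])
  expect_lt(acos(pmin(1, n[3])), 1e-6)
  expect_lt(abs(fit$plane$offset), 1e-9)
})

test_that("RANSAC with the coverage-formula iteration count recovers a 40% plane", {
  # n_iters >= log(0.001)/log(1 - f^3) at f = 0.4
  iters <- ceiling(log(0.001) / log(1 - 0.4^3))
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n_in <- 400
    pts <- rbind(cbind(runif(n_in, -1, 1), runif(n_in, -1, 1), rnorm(n_in, sd = 0.003)),
                 cbind(runif(600, -1, 1), runif(600, -1, 1), runif(600, 0.05, 1)))
    fit <- fit_plane_ransac(point_cloud(pts), 0.01, iters, seed = 1000 + s)
    nrm <- fit$plane$normal * sign(fit$plane$normal[3])
    ok <- acos(pmin(1, nrm[3])) < (1 * pi / 180) && abs(fit$plane$offset) < 0.005
    hits <- hits + ok
  }
  expect_gte(hits, 99)
})

test_that("collinear samples raise a degenerate-input error", {
  line <- point_cloud(cbind(seq_len(10), 0, 0))
  expect_error(fit_plane_ransac(line, 0.01, 50, seed = 1), "collinear")
})

test_that("plane removal matches per-point bookkeeping on a synthetic scene", {
  sc <- small_scene(seed = 12, noise = 0, outliers = 0.02)
  planes <- list(sc$truth$ground_plane, sc$truth$fence_plane)
  trimmed <- remove_planes(sc$cloud, planes, margin = 0)
  # margin 0, noiseless: all ground/fence samples removed, all body kept
  expect_true(all(trimmed$labels %in% c(1L, 4L)))
  expect_equal(sum(trimmed$labels == 1), sum(sc$cloud$labels == 1))

  # brute-force oracle at margin 10 mm on a noisy scene
  sc2 <- small_scene(seed = 13)
  m <- 0.01
  trimmed2 <- remove_planes(sc2$cloud, planes, margin = m)
  keep <- rep(TRUE, n_points(sc2$cloud))
  sd1 <- point_plane_distance(sc2$cloud, planes[[1]], signed = TRUE)
  keep <- keep & abs(sd1) > m
  sd2 <- point_plane_distance(sc2$cloud, planes[[2]], signed = TRUE)
  keep2 <- keep & abs(sd2) > m
  side <- sign(mean(sd2[keep2]))
  keep <- keep2 & sign(sd2) == side
  expect_equal(n_points(trimmed2), sum(keep))
})

test_that("plane removal warns when nothing survives", {
  flat <- point_cloud(cbind(runif(20), runif(20), 0))
  expect_warning(remove_planes(flat, list(plane(c(0, 0, 1), 0)), margin = 0.1),
                 "no points")
})

test_that("statistical outlier removal drops isolated points only", {
  set.seed(5)
  cluster <- matrix(rnorm(300, sd = 0.05), ncol = 3)
  lone <- c(5, 5, 5)
  filtered <- remove_outliers(point_cloud(rbind(cluster, lone)),
                              k_neighbors = 5, std_ratio = 2)
  expect_equal(n_points(filtered), 100)
  expect_false(any(apply(filtered$points, 1, function(p) all(p == lone))))
  # homogeneous grid: nothing removed under a generous ratio
  g <- as.matrix(expand.grid(1:5, 1:5, 1:4))
  expect_equal(n_points(remove_outliers(point_cloud(g), 6, 3)), 100)
  expect_error(remove_outliers(point_cloud(g), 100, 2), "smaller")
})

test_that("outlier removal equals the exhaustive k-NN oracle", {
  sc <- small_scene(seed = 17, n = 800)
  k <- 10; ratio <- 1.5
  filtered <- remove_outliers(sc$cloud, k, ratio)
  D <- as.matrix(dist(sc$cloud$points))
  diag(D) <- Inf
  md <- apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
  keep <- md <= mean(md) + ratio * sd(md)
  expect_equal(filtered$points, sc$cloud$points[keep, , drop = FALSE])
})

test_that("normalization maps the ground to z = 0 and is idempotent", {
  sc <- small_scene(seed = 19, noise = 0, outliers = 0)
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  n1 <- normalize_coordinates(body, sc$truth$ground_plane)
  # scene is generated in the canonical frame: near-identity up to centering
  n2 <- normalize_coordinates(n1$cloud, plane(c(0, 0, 1), 0))
  expect_equal(n2$transform$matrix, diag(4), tolerance = 1e-6)
  # ground samples land on z = 0
  ground <- subset_cloud(sc$cloud, sc$cloud$labels == 2)
  gz <- apply_transform(ground$points, n1$transform)[, 3]
  expect_lt(max(abs(gz)), 1e-9)
})

test_that("normalization undoes a random rigid motion up to the heading rule", {
  sc <- small_scene(seed = 23, noise = 0, outliers = 0)
  body <- subset_cloud(sc$cloud, sc$cloud$labels == 1)
  ref <- normalize_coordinates(body, sc$truth$ground_plane)
  for (s in 1:3) {
    tf <- rand_rigid(seed = 40 + s, max_angle = pi, max_trans = 2)
    moved <- apply_transform(body, tf)
    gmoved <- with(sc$truth$ground_plane, {
      R <- tf$matrix[1:3, 1:3]; tr <- tf$matrix[1:3, 4]
      n2 <- drop(R %*% normal)
      plane(n2, offset - sum(n2 * tr))
    })
    out <- normalize_coordinates(moved, gmoved)
    expect_equal(out$cloud$points, ref$cloud$points, tolerance = 1e-6)
  }
})
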