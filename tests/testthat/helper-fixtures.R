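# shared fixtures: random clouds, random rigid motions, small scenes

rand_cloud <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  point_cloud(matrix(stats::rnorm(3 * n, sd = scale), ncol = 3))
}

rand_rigid <- function(seed = 1, max_angle = pi, max_trans = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_angle, max_angle)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  rigid_transform_rt(R, stats::runif(3, -max_trans, max_trans))
}

# small, fast scene for tests that only need plausible geometry
small_scene <- function(seed = 1, noise = 0.005, outliers = 0.02, n = 2000) {
  generate_scene(cow_template(noise_sigma = noise, outlier_fraction = outliers,
                              points_per_scene = n, seed = seed))
}

rotation_angle <- function(R) acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
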