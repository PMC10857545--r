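# Parametric generator of cow-shaped scenes. The body is a union of analytic
# primitives (ellipsoid torso, sphere head, cylinder legs and teats) standing
# on a ground plane beside a fence plane, with isotropic Gaussian sensor
# noise on surface points and uniform sparse outliers. Because every
# primitive is analytic, the ground-truth keypoints and measurements are
# closed-form and exact.

#' Parameters of a synthetic cow scene
#'
#' All lengths in meters. The defaults describe a Holstein-sized animal whose
#' ground-truth measurements sit at realistic conformation values (stature
#' 142 cm, hip 6.06 cm above the pins, rump width 11.7 cm, front teats
#' 4.06/4.26 cm).
#'
#' @param body_length torso length (ellipsoid axis along the body).
#' @param body_radius torso half-width and half-height.
#' @param back_height height of the highest point of the back above ground.
#' @param hip_height height of the left hook bone A1 (h1 truth).
#' @param pin_height height of the left pin bone A2 (h2 truth).
#' @param rump_width distance between the inner ischium points C1, C2.
#' @param teat_length_left,teat_length_right front teat lengths.
#' @param leg_radius leg cylinder radius.
#' @param fence_offset distance from the body midline to the fence plane.
#' @param noise_sigma isotropic Gaussian noise sd on surface points.
#' @param outlier_fraction fraction of scene points that are uniform
#'   outliers, in \[0, 1\].
#' @param points_per_scene total number of points in the scene.
#' @param seed integer RNG seed for the scene.
#' @return an object of class `cow_template`.
#' @export
cow_template <- function(body_length = 1.6, body_radius = 0.35,
                         back_height = 1.42, hip_height = 1.30,
                         pin_height = 1.2394, rump_width = 0.117,
                         teat_length_left = 0.0406,
                         teat_length_right = 0.0426,
                         leg_radius = 0.045, fence_offset = 1.0,
                         noise_sigma = 0.005, outlier_fraction = 0.02,
                         points_per_scene = 6000, seed = 1L) {
  tpl <- list(body_length = body_length, body_radius = body_radius,
              back_height = back_height, hip_height = hip_height,
              pin_height = pin_height, rump_width = rump_width,
              teat_length_left = teat_length_left,
              teat_length_right = teat_length_right,
              leg_radius = leg_radius, fence_offset = fence_offset,
              noise_sigma = noise_sigma,
              outlier_fraction = outlier_fraction,
              points_per_scene = as.integer(points_per_scene),
              seed = as.integer(seed))
  lens <- c("body_length", "body_radius", "back_height", "hip_height",
            "pin_height", "rump_width", "teat_length_left",
            "teat_length_right", "leg_radius", "fence_offset")
  for (f in lens)
    if (!is.numeric(tpl[[f]]) || tpl[[f]] <= 0)
      stop("template field '", f, "' must be a positive length")
  if (tpl$noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  if (tpl$outlier_fraction < 0 || tpl$outlier_fraction > 1)
    stop("'outlier_fraction' must lie in [0, 1]")
  if (tpl$points_per_scene < 100)
    stop("'points_per_scene' must be at least 100")
  if (!(tpl$back_height > tpl$hip_height))
    stop("infeasible geometry: back_height must exceed hip_height")
  structure(tpl, class = "cow_template")
}

#' @export
print.cow_template <- function(x, ...) {
  cat(sprintf(paste0("<cow_template> stature %.1f cm, rump offset %.2f cm, ",
                     "rump width %.1f cm, teats %.2f/%.2f cm, %d points, seed %d\n"),
              100 * x$back_height, 100 * (x$hip_height - x$pin_height),
              100 * x$rump_width, 100 * x$teat_length_left,
              100 * x$teat_length_right, x$points_per_scene, x$seed))
  invisible(x)
}

# z on the torso surface below/above the centre at horizontal position (x, y)
.torso_z <- function(x, y, a, b, c, zc, lower = TRUE) {
  arg <- 1 - (x / a)^2 - (y / b)^2
  if (arg <= 0) return(NA_real_)
  zc + (if (lower) -1 else 1) * c * sqrt(arg)
}

# y > 0 on the torso surface at longitudinal position x and height z
.torso_y <- function(x, z, a, b, c, zc) {
  arg <- 1 - (x / a)^2 - ((z - zc) / c)^2
  if (arg <= 0) return(NA_real_)
  b * sqrt(arg)
}

# resolve the analytic geometry: primitives, keypoints, truth measurements
.cow_geometry <- function(tpl) {
  a <- tpl$body_length / 2
  b <- c <- tpl$body_radius
  zc <- tpl$back_height - c
  if (zc <= 0) stop("infeasible geometry: torso centre below the ground")
  x_hook <- -0.5 * a
  x_pin <- -0.7 * a
  y_hook <- .torso_y(x_hook, tpl$hip_height, a, b, c, zc)
  if (is.na(y_hook))
    stop("infeasible geometry: hip_height does not intersect the torso at the hook station")
  y_pin <- .torso_y(x_pin, tpl$pin_height, a, b, c, zc)
  if (is.na(y_pin))
    stop("infeasible geometry: pin_height does not intersect the torso at the pin station")
  z_isch <- .torso_z(x_hook, tpl$rump_width / 2, a, b, c, zc, lower = TRUE)
  if (is.na(z_isch))
    stop("infeasible geometry: rump_width does not fit the torso cross-section")
  x_teat <- 0.45 * a
  y_teat <- 0.06
  z_attach <- .torso_z(x_teat, y_teat, a, b, c, zc, lower = TRUE)
  if (is.na(z_attach))
    stop("infeasible geometry: teat attachment misses the torso")
  zb_l <- z_attach - tpl$teat_length_left
  zb_r <- z_attach - tpl$teat_length_right
  if (zb_l <= 0 || zb_r <= 0)
    stop("infeasible geometry: teat extends below the ground")
  if (!(min(tpl$hip_height, tpl$pin_height) > z_attach))
    stop("infeasible geometry: hip/pin heights must exceed the teat attachment height")
  head_r <- min(0.17, 0.5 * b + 0.025)
  head_ctr <- c(a + 0.5 * head_r, 0, zc + 0.35 * c)
  leg_xy <- rbind(c(0.55 * a, 0.4 * b), c(0.55 * a, -0.4 * b),
                  c(-0.55 * a, 0.4 * b), c(-0.55 * a, -0.4 * b))
  leg_top <- apply(leg_xy, 1, function(p) .torso_z(p[1], p[2], a, b, c, zc, TRUE)) + 0.05
  if (any(is.na(leg_top))) stop("infeasible geometry: leg station misses the torso")

  kpts <- rbind(
    highest_back = c(0, 0, tpl$back_height),
    hook_A1 = c(x_hook, y_hook, tpl$hip_height),
    aux_B1 = c(x_hook, -y_hook, tpl$hip_height),
    pin_A2 = c(x_pin, y_pin, tpl$pin_height),
    aux_B2 = c(x_pin, -y_pin, tpl$pin_height),
    ischium_C1 = c(x_hook, tpl$rump_width / 2, z_isch),
    ischium_C2 = c(x_hook, -tpl$rump_width / 2, z_isch),
    teat_left_top = c(x_teat, y_teat, z_attach),
    teat_left_bottom = c(x_teat, y_teat, zb_l),
    teat_right_top = c(x_teat, -y_teat, z_attach),
    teat_right_bottom = c(x_teat, -y_teat, zb_r))
  # the pelvic landmarks are bony prominences on a live animal; each carries
  # a small hemispherical boss centred on the landmark so the surface
  # geometry actually encodes its position (a featureless surface would make
  # the detection task ill-posed)
  boss_names <- c("hook_A1", "aux_B1", "pin_A2", "aux_B2",
                  "ischium_C1", "ischium_C2")
  boss_r <- c(0.02, 0.02, 0.02, 0.02, 0.015, 0.015)
  boss_ctr <- kpts[boss_names, , drop = FALSE]
  boss_nrm <- t(apply(boss_ctr, 1, function(k) {
    u <- c(k[1] / a^2, k[2] / b^2, (k[3] - zc) / c^2)
    u / sqrt(sum(u^2))
  }))
  list(a = a, b = b, c = c, zc = zc, head_r = head_r, head_ctr = head_ctr,
       leg_xy = leg_xy, leg_top = leg_top, teat_r = 0.012,
       x_teat = x_teat, y_teat = y_teat, z_attach = z_attach,
       zb_l = zb_l, zb_r = zb_r,
       boss_ctr = boss_ctr, boss_nrm = boss_nrm, boss_r = boss_r,
       keypoints = keypoint_set(rownames(kpts), kpts))
}

# hemispherical boss: points on the sphere of radius r around ctr, reflected
# to the outward side of the surface normal u
.sample_boss <- function(n, ctr, u, r) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  d <- matrix(stats::rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  s <- sign(d %*% u)
  s[s == 0] <- 1
  d <- d * as.vector(s)
  sweep(r * d, 2, ctr, `+`)
}

.sample_ellipsoid <- function(n, a, b, c, centre) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  wmax <- max(b * c, a * c, a * b)
  while (got < n) {
    m <- max(2L * (n - got), 32L)
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    w <- sqrt((u[, 1] * b * c)^2 + (u[, 2] * a * c)^2 + (u[, 3] * a * b)^2)
    acc <- stats::runif(m) < w / wmax
    take <- min(sum(acc), n - got)
    if (take > 0) {
      sel <- which(acc)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(a * u[sel, 1], b * u[sel, 2], c * u[sel, 3])
      got <- got + take
    }
  }
  sweep(out, 2, centre, `+`)
}

.sample_sphere <- function(n, r, centre) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(r * u, 2, centre, `+`)
}

.sample_cylinder <- function(n, r, x, y, z0, z1) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x + r * cos(th), y + r * sin(th), stats::runif(n, z0, z1))
}

.sample_disk <- function(n, r, x, y, z) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(x + rr * cos(th), y + rr * sin(th), rep(z, n))
}

.sample_rect <- function(n, xr, yr, zr) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  cbind(stats::runif(n, xr[1], xr[2]), stats::runif(n, yr[1], yr[2]),
        stats::runif(n, zr[1], zr[2]))
}

# largest-remainder apportionment of n among weights w
.apportion <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate one synthetic cow scene
#'
#' @param template a [cow_template()].
#' @return list with `cloud` (a labelled, colored [point_cloud()]; labels
#'   1 = body, 2 = ground, 3 = fence, 4 = outlier) and `truth` (class
#'   `cow_ground_truth`: analytic keypoints, measurements in cm, ground and
#'   fence [plane()]s, and the template). Identical seeds give identical
#'   scenes.
#' @examples
#' sc <- generate_scene(cow_template(points_per_scene = 1000, seed = 7))
#' sc$truth$measurements
#' @export
generate_scene <- function(template) {
  if (!inherits(template, "cow_template"))
    template <- do.call(cow_template, as.list(template))
  geo <- .cow_geometry(template)
  local_rng(template$seed)
  N <- template$points_per_scene
  n_out <- round(template$outlier_fraction * N)
  n_surf <- N - n_out
  n_ground <- round(0.20 * n_surf)
  n_fence <- round(0.12 * n_surf)
  n_body <- n_surf - n_ground - n_fence

  a <- geo$a; b <- geo$b; c <- geo$c; zc <- geo$zc
  leg_h <- geo$leg_top
  areas <- c(
    torso = 4 * pi * (((a * b)^1.6075 + (a * c)^1.6075 + (b * c)^1.6075) / 3)^(1 / 1.6075),
    head = 4 * pi * geo$head_r^2,
    leg1 = 2 * pi * template$leg_radius * leg_h[1],
    leg2 = 2 * pi * template$leg_radius * leg_h[2],
    leg3 = 2 * pi * template$leg_radius * leg_h[3],
    leg4 = 2 * pi * template$leg_radius * leg_h[4],
    teat_l = 2 * pi * geo$teat_r * template$teat_length_left + pi * geo$teat_r^2,
    teat_r = 2 * pi * geo$teat_r * template$teat_length_right + pi * geo$teat_r^2,
    boss1 = 2 * pi * geo$boss_r[1]^2, boss2 = 2 * pi * geo$boss_r[2]^2,
    boss3 = 2 * pi * geo$boss_r[3]^2, boss4 = 2 * pi * geo$boss_r[4]^2,
    boss5 = 2 * pi * geo$boss_r[5]^2, boss6 = 2 * pi * geo$boss_r[6]^2)
  m <- length(geo$keypoints$names)
  n_prim <- n_body - m  # the exact keypoints are appended as body samples
  cnt <- .apportion(n_prim, areas)
  # teats and landmark bosses are tiny but are measurement targets:
  # guarantee coverage, as a capture focused on the scored regions would
  floor_teat <- min(40L, n_prim %/% 20L)
  floor_boss <- min(25L, n_prim %/% 40L)
  for (j in c(7L, 8L)) if (cnt[j] < floor_teat) {
    cnt[1L] <- cnt[1L] - (floor_teat - cnt[j])
    cnt[j] <- floor_teat
  }
  for (j in 9L:14L) if (cnt[j] < floor_boss) {
    cnt[1L] <- cnt[1L] - (floor_boss - cnt[j])
    cnt[j] <- floor_boss
  }
  body <- rbind(
    .sample_ellipsoid(cnt[1], a, b, c, c(0, 0, zc)),
    .sample_sphere(cnt[2], geo$head_r, geo$head_ctr),
    .sample_cylinder(cnt[3], template$leg_radius, geo$leg_xy[1, 1], geo$leg_xy[1, 2], 0, leg_h[1]),
    .sample_cylinder(cnt[4], template$leg_radius, geo$leg_xy[2, 1], geo$leg_xy[2, 2], 0, leg_h[2]),
    .sample_cylinder(cnt[5], template$leg_radius, geo$leg_xy[3, 1], geo$leg_xy[3, 2], 0, leg_h[3]),
    .sample_cylinder(cnt[6], template$leg_radius, geo$leg_xy[4, 1], geo$leg_xy[4, 2], 0, leg_h[4]),
    rbind(.sample_cylinder(max(cnt[7] - 8, 0), geo$teat_r, geo$x_teat, geo$y_teat, geo$zb_l, geo$z_attach),
          .sample_disk(min(cnt[7], 8), geo$teat_r, geo$x_teat, geo$y_teat, geo$zb_l)),
    rbind(.sample_cylinder(max(cnt[8] - 8, 0), geo$teat_r, geo$x_teat, -geo$y_teat, geo$zb_r, geo$z_attach),
          .sample_disk(min(cnt[8], 8), geo$teat_r, geo$x_teat, -geo$y_teat, geo$zb_r)),
    do.call(rbind, lapply(1:6, function(j)
      .sample_boss(cnt[8L + j], geo$boss_ctr[j, ], geo$boss_nrm[j, ],
                   geo$boss_r[j]))),
    unname(geo$keypoints$points))

  gr_x <- c(-a - 0.6, a + 0.8)
  gr_y <- c(-template$fence_offset - 0.4, 0.8)
  ground <- .sample_rect(n_ground, gr_x, gr_y, c(0, 0))
  fence <- .sample_rect(n_fence, gr_x, c(-template$fence_offset, -template$fence_offset),
                        c(0, template$back_height + 0.3))

  if (template$noise_sigma > 0) {
    body <- body + stats::rnorm(length(body), sd = template$noise_sigma)
    ground <- ground + stats::rnorm(length(ground), sd = template$noise_sigma)
    fence <- fence + stats::rnorm(length(fence), sd = template$noise_sigma)
  }
  clean <- rbind(body, ground, fence)
  lo <- apply(clean, 2, min); hi <- apply(clean, 2, max)
  pad <- 0.2 * (hi - lo)
  outl <- .sample_rect(n_out, c(lo[1] - pad[1], hi[1] + pad[1]),
                       c(lo[2] - pad[2], hi[2] + pad[2]),
                       c(lo[3] - pad[3], hi[3] + pad[3]))
  pts <- rbind(body, ground, fence, outl)
  labels <- rep(1:4, times = c(nrow(body), nrow(ground), nrow(fence), nrow(outl)))
  pal <- rbind(c(0.80, 0.64, 0.46), c(0.42, 0.54, 0.32),
               c(0.55, 0.55, 0.58), c(0.85, 0.20, 0.20))
  cloud <- point_cloud(pts, colors = pal[labels, , drop = FALSE], labels = labels)

  truth <- structure(list(
    keypoints = geo$keypoints,
    measurements = c(
      stature_cm = 100 * template$back_height,
      rump_angle_cm = 100 * (template$hip_height - template$pin_height),
      rump_width_cm = 100 * template$rump_width,
      teat_left_cm = 100 * template$teat_length_left,
      teat_right_cm = 100 * template$teat_length_right,
      teat_avg_cm = 100 * (template$teat_length_left + template$teat_length_right) / 2),
    ground_plane = plane(c(0, 0, 1), 0),
    fence_plane = plane(c(0, 1, 0), template$fence_offset),
    template = template), class = "cow_ground_truth")
  list(cloud = cloud, truth = truth)
}

#' @export
print.cow_ground_truth <- function(x, ...) {
  cat("<cow_ground_truth>\n")
  print(round(x$measurements, 3))
  invisible(x)
}

#' Default per-field sampling ranges for training scenes
#'
#' Measurement-bearing fields span the 9-level score tables (stature
#' 128-152 cm, rump width 5-17 cm, teat length 2-10 cm) while hook and pin
#' heights cover hip-pin offsets of roughly -3 to +15 cm; the remaining
#' fields are held at the template defaults.
#'
#' @return named list of `c(lo, hi)` intervals.
#' @export
default_template_ranges <- function() {
  d <- cow_template()
  list(back_height = c(1.28, 1.52),
       hip_height = c(1.14, 1.21),
       pin_height = c(1.06, 1.17),
       rump_width = c(0.05, 0.17),
       teat_length_left = c(0.02, 0.10),
       teat_length_right = c(0.02, 0.10),
       body_length = c(1.5, 1.7),
       noise_sigma = c(d$noise_sigma, d$noise_sigma),
       outlier_fraction = c(d$outlier_fraction, d$outlier_fraction),
       points_per_scene = c(d$points_per_scene, d$points_per_scene))
}

#' Generate a reproducible set of training scenes
#'
#' Template fields are drawn independently and uniformly from the given
#' intervals; every other field keeps its [cow_template()] default.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param template_ranges named list of `c(lo, hi)` intervals over
#'   [cow_template()] fields (default [default_template_ranges()]).
#' @param seed integer seed controlling both the field draws and the
#'   per-scene generation seeds.
#' @return list of `n_scenes` elements, each as returned by
#'   [generate_scene()].
#' @export
generate_training_set <- function(n_scenes, template_ranges = default_template_ranges(),
                                  seed = 1L) {
  if (n_scenes < 1) stop("'n_scenes' must be at least 1")
  tplf <- names(formals(cow_template))
  for (f in names(template_ranges)) {
    r <- template_ranges[[f]]
    if (!f %in% tplf) stop("unknown template field in ranges: '", f, "'")
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid (empty) range for field '", f, "'")
  }
  local_rng(seed)
  fields <- names(template_ranges)
  draws <- sapply(fields, function(f)
    stats::runif(n_scenes, template_ranges[[f]][1], template_ranges[[f]][2]))
  draws <- matrix(draws, nrow = n_scenes, dimnames = list(NULL, fields))
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
  lapply(seq_len(n_scenes), function(i) {
    args <- as.list(draws[i, ])
    if ("points_per_scene" %in% fields)
      args$points_per_scene <- round(args$points_per_scene)
    args$seed <- scene_seeds[i]
    generate_scene(do.call(cow_template, args))
  })
}

#' Export a scene as PLY plus ground-truth JSON sidecar
#'
#' @param scene a list as returned by [generate_scene()].
#' @param basename output path without extension; writes `<basename>.ply`
#'   and `<basename>.json`.
#' @param binary passed to [write_ply()].
#' @return the two paths, invisibly.
#' @export
write_scene <- function(scene, basename, binary = TRUE) {
  ply <- paste0(basename, ".ply")
  js <- paste0(basename, ".json")
  write_ply(scene$cloud, ply, binary = binary)
  tr <- scene$truth
  obj <- list(
    keypoints = stats::setNames(lapply(seq_along(tr$keypoints$names),
                                       function(i) unname(tr$keypoints$points[i, ])),
                                tr$keypoints$names),
    measurements = as.list(tr$measurements),
    ground_plane = list(normal = tr$ground_plane$normal, offset = tr$ground_plane$offset),
    fence_plane = list(normal = tr$fence_plane$normal, offset = tr$fence_plane$offset),
    template = unclass(tr$template))
  jsonlite::write_json(obj, js, auto_unbox = TRUE, digits = NA)
  invisible(c(ply = ply, json = js))
}
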