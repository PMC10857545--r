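# Scene preprocessing: voxel-grid downsampling, RANSAC extraction of the
# ground and fence planes, plane/half-space trimming, statistical outlier
# removal and normalization of the animal into a canonical frame (ground at
# z = 0, body axis along x).

#' Construct an implicit plane
#'
#' The plane a x + b y + c z + d = 0, stored as a unit normal
#' `n = (a, b, c)` and offset `d`, so a point `x` lies on the plane iff
#' `n . x = -d`.
#'
#' @param normal length-3 normal vector (normalized internally).
#' @param offset scalar offset d in meters (for the *unit* normal).
#' @return an object of class `plane`.
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  if (length(normal) != 3 || !all(is.finite(normal)))
    stop("'normal' must be a finite 3-vector")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("'normal' must be non-zero")
  structure(list(normal = normal / nn, offset = as.numeric(offset) / nn),
            class = "plane")
}

#' @rdname plane
#' @param x object to test.
#' @export
is_plane <- function(x) inherits(x, "plane")

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> %.4f x + %.4f y + %.4f z + %.4f = 0\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Point-to-plane distance
#'
#' @param point a 3-vector, an n x 3 matrix, or a `point_cloud`.
#' @param plane a [plane()].
#' @param signed return the signed distance `n . x + d` instead of its
#'   absolute value.
#' @return non-negative distances in meters (or signed if requested).
#' @export
point_plane_distance <- function(point, plane, signed = FALSE) {
  if (!is_plane(plane)) stop("'plane' must be a plane object")
  pts <- if (is_point_cloud(point)) point$points
         else if (is.null(dim(point))) matrix(point, ncol = 3)
         else as.matrix(point)
  d <- drop(pts %*% plane$normal) + plane$offset
  if (signed) d else abs(d)
}

#' Voxel-grid downsampling
#'
#' Space is partitioned into cubes of edge `voxel_size`; each occupied voxel
#' contributes one output point at the centroid of its members. Voxel indices
#' are the floor of coordinate / voxel_size, so the result does not depend on
#' the input point order.
#'
#' @param cloud a [point_cloud()].
#' @param voxel_size cube edge in meters (> 0).
#' @return the downsampled `point_cloud` (colors/labels dropped; the output
#'   points are synthesized centroids).
#' @export
voxel_downsample <- function(cloud, voxel_size) {
  stopifnot(is_point_cloud(cloud))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("'voxel_size' must be a positive scalar")
  pts <- cloud$points
  if (nrow(pts) <= 1) return(point_cloud(pts))
  key <- floor(pts / voxel_size)
  id <- paste(key[, 1], key[, 2], key[, 3])
  # order voxels deterministically by their integer index for reproducibility
  ux <- rowsum(pts, group = id)
  cnt <- as.vector(table(id)[rownames(ux)])
  cent <- ux / cnt
  ord <- order(rownames(ux))
  point_cloud(unname(cent[ord, , drop = FALSE]))
}

#' RANSAC plane fit
#'
#' Repeatedly samples three points, forms the plane through them and counts
#' points within `dist_thresh`; the plane with the largest inlier set wins
#' and is refit to its inliers by total least squares before return.
#'
#' @param cloud a [point_cloud()] with at least 3 points.
#' @param dist_thresh inlier distance threshold in meters (default 0.015,
#'   matched to depth-camera noise of about 1 cm at working range).
#' @param n_iters number of random triples to try (default 1000).
#' @param seed optional integer; when given, the sampling is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a list with `plane` (a [plane()]) and `inliers` (integer index
#'   vector into the cloud).
#' @export
fit_plane_ransac <- function(cloud, dist_thresh = 0.015, n_iters = 1000,
                             seed = NULL) {
  stopifnot(is_point_cloud(cloud))
  pts <- cloud$points
  n <- nrow(pts)
  if (n < 3) stop("plane fitting needs at least 3 points")
  if (dist_thresh <= 0) stop("'dist_thresh' must be positive")
  if (n_iters < 1) stop("'n_iters' must be at least 1")
  local_rng(seed)
  # all triples at once: n_iters x 3 index matrix
  tri <- matrix(sample.int(n, 3L * n_iters, replace = TRUE), ncol = 3)
  p1 <- pts[tri[, 1], , drop = FALSE]
  e1 <- pts[tri[, 2], , drop = FALSE] - p1
  e2 <- pts[tri[, 3], , drop = FALSE] - p1
  nr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nr^2))
  ok <- len > 1e-12
  if (!any(ok)) stop("degenerate input: all sampled triples were collinear")
  nr <- nr[ok, , drop = FALSE] / len[ok]
  d0 <- -rowSums(nr * p1[ok, , drop = FALSE])
  # count inliers per candidate in blocks to bound memory
  best_count <- -1L; best <- NULL
  idx <- seq_len(nrow(nr))
  for (blk in split(idx, ceiling(idx / 256))) {
    dm <- abs(pts %*% t(nr[blk, , drop = FALSE]) +
                matrix(d0[blk], n, length(blk), byrow = TRUE))
    counts <- colSums(dm <= dist_thresh)
    j <- which.max(counts)
    if (counts[j] > best_count) {
      best_count <- counts[j]
      best <- c(nr[blk[j], ], d0[blk[j]])
    }
  }
  # trimmed total-least-squares refit: re-estimate on the inliers, shrinking
  # the selection to 3x the inlier RMS (capped at dist_thresh) until the set
  # stabilizes. This rejects grazing off-plane points (e.g. the bottom of a
  # leg standing on the ground) that a single refit would average in.
  fitted <- plane(best[1:3], best[4])
  inl <- integer(0)
  thr <- dist_thresh
  for (it in 1:10) {
    new_inl <- which(point_plane_distance(pts, fitted) <= thr)
    if (length(new_inl) < 3 || identical(new_inl, inl)) break
    inl <- new_inl
    fitted <- fit_plane_lsq(pts[inl, , drop = FALSE])
    if (sum(fitted$normal * best[1:3]) < 0)
      fitted <- plane(-fitted$normal, -fitted$offset)
    rms <- sqrt(mean(point_plane_distance(pts[inl, , drop = FALSE], fitted)^2))
    thr <- min(dist_thresh, max(3 * rms, 1e-8))
  }
  inl <- which(point_plane_distance(pts, fitted) <= dist_thresh)
  list(plane = fitted, inliers = inl)
}

#' Total least squares plane through a set of points
#' @param pts n x 3 coordinate matrix (n >= 3, not collinear).
#' @return a [plane()].
#' @export
fit_plane_lsq <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) stop("plane fitting needs at least 3 points")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normal <- sv$v[, 3]
  plane(normal, -sum(normal * ctr))
}

#' Remove plane points and trim beyond the fence
#'
#' Drops every point within `margin` of any plane in `planes`. For each plane
#' after the first (the fences), the half-space not containing the centroid
#' of the ground-cleared cloud is removed as well, so everything on the far
#' side of a fence goes away.
#'
#' @param cloud a [point_cloud()].
#' @param planes a list of [plane()] objects; by convention the first is the
#'   ground and the rest are fences.
#' @param margin trim distance in meters (default 0.01).
#' @return the trimmed `point_cloud`; an empty result triggers a warning.
#' @export
remove_planes <- function(cloud, planes, margin = 0.01) {
  stopifnot(is_point_cloud(cloud))
  if (is_plane(planes)) planes <- list(planes)
  if (margin < 0) stop("'margin' must be non-negative")
  keep <- rep(TRUE, n_points(cloud))
  for (k in seq_along(planes)) {
    pl <- planes[[k]]
    sd <- point_plane_distance(cloud, pl, signed = TRUE)
    keep <- keep & abs(sd) > margin
    if (k > 1) {
      ctr_side <- sign(sum(sd[keep]) / max(1, sum(keep)))
      if (ctr_side != 0) keep <- keep & sign(sd) == ctr_side
    }
  }
  if (!any(keep)) warning("remove_planes: no points survived trimming")
  subset_cloud(cloud, keep)
}

#' Statistical outlier removal
#'
#' For every point the mean distance to its `k_neighbors` nearest neighbours
#' is computed; points whose statistic exceeds the global mean plus
#' `std_ratio` standard deviations are dropped.
#'
#' @param cloud a [point_cloud()] with more than `k_neighbors` points.
#' @param k_neighbors neighbourhood size (default 20).
#' @param std_ratio cut-off in standard deviations (default 2.0).
#' @return the filtered `point_cloud`.
#' @export
remove_outliers <- function(cloud, k_neighbors = 20, std_ratio = 2.0) {
  stopifnot(is_point_cloud(cloud))
  n <- n_points(cloud)
  if (k_neighbors < 1) stop("'k_neighbors' must be at least 1")
  if (k_neighbors >= n) stop("'k_neighbors' must be smaller than the point count")
  md <- knn_mean_dist_cpp(cloud$points, as.integer(k_neighbors))
  cut <- mean(md) + std_ratio * stats::sd(md)
  subset_cloud(cloud, md <= cut)
}

#' Normalize a body cloud into the canonical frame
#'
#' Computes the rigid transform that maps the ground normal to +z and the
#' ground plane to z = 0, then rotates about z so the first principal
#' component of the xy-projected points lies along x. The 180-degree heading
#' ambiguity is resolved by putting the end with more points in its outer
#' quarter of the body axis (the head end, which carries the head's extra
#' surface) at +x; exact ties keep the current heading.
#'
#' @param cloud the body `point_cloud` (planes already removed).
#' @param ground the ground [plane()].
#' @return list with `cloud` (normalized) and `transform` (the
#'   `rigid_transform` that was applied).
#' @export
normalize_coordinates <- function(cloud, ground) {
  stopifnot(is_point_cloud(cloud), is_plane(ground))
  if (n_points(cloud) < 3) stop("normalization needs at least 3 points")
  n <- ground$normal
  # orient the normal toward the cloud so the animal ends up at z > 0
  if (mean(point_plane_distance(cloud, ground, signed = TRUE)) < 0) {
    n <- -n
    ground <- plane(n, -ground$offset)
  }
  # rotation taking n to +z (Rodrigues between unit vectors)
  z <- c(0, 0, 1)
  v <- c(n[2] * z[3] - n[3] * z[2], n[3] * z[1] - n[1] * z[3], n[1] * z[2] - n[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(n * z)
  R1 <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  t1 <- rigid_transform_rt(R1, c(0, 0, ground$offset))  # plane n.x+d=0 -> z=0
  pts1 <- apply_transform(cloud$points, t1)
  # principal horizontal axis from the xy covariance
  xy <- sweep(pts1[, 1:2, drop = FALSE], 2, colMeans(pts1[, 1:2, drop = FALSE]))
  ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  ang <- atan2(ax[2], ax[1])
  t2 <- rotation_about_axis("z", -ang)
  pts2 <- apply_transform(pts1, t2)
  # center x/y on the body, keep z anchored at the ground
  ctr <- colMeans(pts2)
  t3 <- rigid_transform_rt(diag(3), c(-ctr[1], -ctr[2], 0))
  pts3 <- apply_transform(pts2, t3)
  # heading disambiguation: more points in the outer front quarter => head at +x
  rngx <- range(pts3[, 1]); span <- diff(rngx)
  front <- sum(pts3[, 1] > rngx[2] - 0.25 * span)
  back <- sum(pts3[, 1] < rngx[1] + 0.25 * span)
  tf <- transform_compose(t3, transform_compose(t2, t1))
  if (back > front) {
    flip <- rotation_about_axis("z", pi)
    tf <- transform_compose(flip, tf)
    pts3 <- apply_transform(pts3, flip)
  }
  out <- cloud
  out$points <- pts3
  colnames(out$points) <- c("x", "y", "z")
  list(cloud = out, transform = tf)
}

# seed the calling function's RNG temporarily; caller's state is restored
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}
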