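#' Construct a point cloud
#'
#' The basic container used throughout the package: an ordered set of 3D
#' points in meters, with optional per-point RGB colors and integer labels.
#'
#' @param points numeric matrix with 3 columns (x, y, z) in meters, or a
#'   numeric vector of length 3 for a single point. A 0-row matrix gives an
#'   empty cloud.
#' @param colors optional numeric matrix with 3 columns, values in \[0, 1\],
#'   one row per point.
#' @param labels optional integer vector, one entry per point.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(points, colors = NULL, labels = NULL) {
  if (is.null(dim(points))) {
    if (length(points) == 0) {
      points <- matrix(numeric(0), ncol = 3)
    } else if (length(points) == 3) {
      points <- matrix(points, ncol = 3)
    } else {
      stop("'points' must be an n x 3 matrix")
    }
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("'points' must have exactly 3 columns")
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("all coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  n <- nrow(points)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "double"
    if (ncol(colors) != 3 || nrow(colors) != n)
      stop("'colors' must be an n x 3 matrix matching the points")
    if (n > 0 && (any(colors < 0) || any(colors > 1)))
      stop("'colors' must lie in [0, 1]")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n)
      stop("'labels' must have one entry per point")
  }
  structure(list(points = points, colors = colors, labels = labels),
            class = "point_cloud")
}

#' @rdname point_cloud
#' @param x object to test or print.
#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(is_point_cloud(cloud))
  nrow(cloud$points)
}

#' @param ... ignored.
#' @rdname point_cloud
#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s\n", nrow(x$points),
              if (!is.null(x$colors)) ", rgb" else "",
              if (!is.null(x$labels)) ", labelled" else ""))
  if (nrow(x$points) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent [m]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
plot.point_cloud <- function(x, which = c("xz", "xy", "yz"), cex = 0.2, ...) {
  which <- match.arg(which)
  i <- match(substr(which, 1, 1), c("x", "y", "z"))
  j <- match(substr(which, 2, 2), c("x", "y", "z"))
  col <- if (!is.null(x$colors)) grDevices::rgb(x$colors) else "grey30"
  graphics::plot(x$points[, i], x$points[, j], asp = 1, pch = 16, cex = cex,
                 col = col, xlab = substr(which, 1, 1),
                 ylab = substr(which, 2, 2), ...)
  invisible(x)
}

#' Subset a point cloud by point index
#' @param cloud a `point_cloud`.
#' @param idx integer or logical index vector.
#' @return the restricted `point_cloud` (colors/labels carried along).
#' @export
subset_cloud <- function(cloud, idx) {
  stopifnot(is_point_cloud(cloud))
  point_cloud(cloud$points[idx, , drop = FALSE],
              colors = if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx])
}

#' Concatenate point clouds
#' @param ... `point_cloud` objects. Colors/labels are kept only when present
#'   on every argument.
#' @return the merged `point_cloud`.
#' @export
concat_clouds <- function(...) {
  cls <- list(...)
  stopifnot(all(vapply(cls, is_point_cloud, logical(1))))
  pts <- do.call(rbind, lapply(cls, `[[`, "points"))
  cols <- NULL
  if (all(vapply(cls, function(c) !is.null(c$colors), logical(1))))
    cols <- do.call(rbind, lapply(cls, `[[`, "colors"))
  labs <- NULL
  if (all(vapply(cls, function(c) !is.null(c$labels), logical(1))))
    labs <- unlist(lapply(cls, `[[`, "labels"))
  point_cloud(pts, colors = cols, labels = labs)
}

# ---- rigid transforms -------------------------------------------------------

#' Construct a rigid transform
#'
#' A 4x4 homogeneous transform whose rotation block is orthonormal with
#' determinant +1 (proper rotation) and whose last row is (0, 0, 0, 1).
#'
#' @param matrix 4x4 numeric matrix.
#' @param tol tolerance for the rigidity check (default 1e-6).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix, tol = 1e-6) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(4, 4))) stop("a rigid transform is a 4 x 4 matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    stop("last row of a rigid transform must be (0, 0, 0, 1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation block must be orthonormal with determinant +1")
  structure(list(matrix = m), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Build a rigid transform from a rotation and a translation
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector in meters.
#' @return a `rigid_transform`.
#' @export
rigid_transform_rt <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  rigid_transform(m)
}

#' Elementary rotations about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle rotation angle in radians.
#' @return a `rigid_transform` with zero translation.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
    y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
    z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
  rigid_transform_rt(R)
}

#' Identity, composition and inverse of rigid transforms
#' @return a `rigid_transform`.
#' @export
transform_identity <- function() rigid_transform(diag(4))

#' @rdname transform_identity
#' @param a,b `rigid_transform` objects; the composite applies `b` first,
#'   then `a` (matrix product `a %*% b`).
#' @export
transform_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$matrix %*% b$matrix)
}

#' @rdname transform_identity
#' @param t a `rigid_transform`.
#' @export
transform_inverse <- function(t) {
  stopifnot(is_rigid_transform(t))
  R <- t$matrix[1:3, 1:3]
  tr <- t$matrix[1:3, 4]
  rigid_transform_rt(t(R), -t(R) %*% tr)
}

#' Apply a rigid transform to a point cloud or point matrix
#'
#' Each point is mapped through homogeneous multiplication; pairwise
#' distances are preserved (rigidity).
#'
#' @param cloud a `point_cloud`, or an n x 3 coordinate matrix.
#' @param t a `rigid_transform`.
#' @return the transformed cloud (or matrix, matching the input type).
#' @export
apply_transform <- function(cloud, t) {
  if (!is_rigid_transform(t)) stop("'t' must be a rigid_transform")
  pts <- if (is_point_cloud(cloud)) cloud$points else as.matrix(cloud)
  R <- t$matrix[1:3, 1:3]
  tr <- t$matrix[1:3, 4]
  out <- sweep(pts %*% t(R), 2, -tr)
  if (is_point_cloud(cloud)) {
    colnames(out) <- c("x", "y", "z")
    cloud$points <- out
    cloud
  } else out
}

#' Factory-calibrated top-camera initialization transform
#'
#' The fixed alignment used to bring clouds captured by the top camera into
#' the bottom camera's frame before local refinement. It is a rotation about
#' the y axis by the angle with cosine 0.642788 and sine 0.766044 (50
#' degrees), combined with a translation of (-1.390930, 0, 0.733545) meters.
#' The constant is centralized here so a recalibration changes one
#' definition.
#'
#' @return a `rigid_transform`.
#' @examples
#' initialization_matrix()$matrix[1, 1]  # 0.642788
#' @export
initialization_matrix <- function() {
  rigid_transform(rbind(
    c(0.642788, 0, 0.766044, -1.390930),
    c(0, 1, 0, 0),
    c(-0.766044, 0, 0.642788, 0.733545),
    c(0, 0, 0, 1)))
}
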