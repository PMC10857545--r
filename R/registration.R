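# Registration between partially overlapping clouds: alignment quality
# metrics (fitness / inlier RMSE), point-to-point ICP with the closed-form
# SVD update, and the fixed-initialization stitch used for the two-camera
# capture rig.

#' Evaluate an alignment between two clouds
#'
#' The source cloud is mapped by `transform`; every mapped source point whose
#' nearest target point lies within `max_corr_dist` is an inlier
#' correspondence. Fitness is the inlier fraction of the source and inlier
#' RMSE the root-mean-square of the inlier distances.
#'
#' @param source,target non-empty [point_cloud()] objects.
#' @param max_corr_dist correspondence distance in meters (default 0.03).
#' @param transform the alignment to score (default identity).
#' @return an object of class `registration_result` with fields `fitness`,
#'   `inlier_rmse`, `correspondence_count` and `transform`.
#' @export
evaluate_registration <- function(source, target, max_corr_dist = 0.03,
                                  transform = transform_identity()) {
  stopifnot(is_point_cloud(source), is_point_cloud(target))
  if (n_points(source) == 0 || n_points(target) == 0)
    stop("registration requires non-empty clouds")
  if (max_corr_dist <= 0) stop("'max_corr_dist' must be positive")
  mapped <- apply_transform(source$points, transform)
  nn <- nn_search_cpp(mapped, target$points)
  inl <- nn$dist <= max_corr_dist
  k <- sum(inl)
  structure(list(
    fitness = k / n_points(source),
    inlier_rmse = if (k > 0) sqrt(mean(nn$dist[inl]^2)) else 0,
    correspondence_count = as.integer(k),
    transform = transform), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> fitness %.3f, inlier RMSE %.4f m (%d correspondences)\n",
              x$fitness, x$inlier_rmse, x$correspondence_count))
  invisible(x)
}

#' Point-to-point ICP
#'
#' Alternates nearest-neighbour correspondence assignment (within
#' `max_corr_dist`) with the closed-form least-squares rigid update obtained
#' from the SVD of the correspondence cross-covariance, until the RMSE
#' improvement drops below `tol` or `max_iter` is reached.
#'
#' @param source,target non-empty [point_cloud()] objects.
#' @param init starting `rigid_transform` (default identity).
#' @param max_corr_dist correspondence distance in meters.
#' @param max_iter iteration cap (default 30).
#' @param tol convergence threshold on the RMSE change (default 1e-6).
#' @return the accumulated `rigid_transform` mapping source onto target.
#' @export
icp_point_to_point <- function(source, target, init = transform_identity(),
                               max_corr_dist = 0.03, max_iter = 30,
                               tol = 1e-6) {
  stopifnot(is_point_cloud(source), is_point_cloud(target))
  if (n_points(source) == 0 || n_points(target) == 0)
    stop("registration requires non-empty clouds")
  tf <- init
  src <- apply_transform(source$points, tf)
  tgt <- target$points
  prev_rmse <- Inf
  for (it in seq_len(max_iter)) {
    nn <- nn_search_cpp(src, tgt)
    sel <- nn$dist <= max_corr_dist
    if (it == 1 && !any(sel))
      stop("no overlap: zero correspondences at the starting alignment")
    if (!any(sel)) break
    a <- src[sel, , drop = FALSE]
    b <- tgt[nn$idx[sel], , drop = FALSE]
    rmse <- sqrt(mean(nn$dist[sel]^2))
    if (prev_rmse - rmse < tol) break
    prev_rmse <- rmse
    ca <- colMeans(a); cb <- colMeans(b)
    H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
    tr <- cb - drop(R %*% ca)
    step <- rigid_transform_rt(R, tr)
    tf <- transform_compose(step, tf)
    src <- apply_transform(src, step)
  }
  tf
}

#' Stitch a top-camera cloud onto a bottom-camera cloud
#'
#' Applies the fixed [initialization_matrix()] to the top cloud, optionally
#' refines with [icp_point_to_point()], and returns the merged cloud together
#' with the alignment evaluation.
#'
#' @param top,bottom non-empty [point_cloud()] objects (top is the moving
#'   source).
#' @param refine run ICP from the initialization (default FALSE).
#' @param max_corr_dist evaluation/ICP correspondence distance in meters.
#' @return list with `cloud` (merged) and `result` (a `registration_result`).
#' @export
stitch_with_initialization <- function(top, bottom, refine = FALSE,
                                       max_corr_dist = 0.03) {
  tf <- initialization_matrix()
  if (refine)
    tf <- icp_point_to_point(top, bottom, init = tf,
                             max_corr_dist = max_corr_dist)
  res <- evaluate_registration(top, bottom, max_corr_dist, tf)
  moved <- apply_transform(top, tf)
  merged <- point_cloud(rbind(moved$points, bottom$points))
  list(cloud = merged, result = res)
}
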