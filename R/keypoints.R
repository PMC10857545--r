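# Ordered, named anatomical keypoints and the distance-field representation
# used to regress them: for a cloud of n points and m keypoints, the n x m
# matrix of Euclidean distances. Keypoints are recovered from a (predicted)
# field as the per-column argmin.

#' Canonical keypoint names
#'
#' The ordered set of anatomical landmarks used by the measurement formulas:
#' the highest point of the back, the left/right hook (hip) bones `A1`/`B1`,
#' the left/right pin bones `A2`/`B2`, the inner ischium edges `C1`/`C2`
#' bounding the rump width, and top/bottom of each front teat.
#'
#' @return character vector of length 11.
#' @export
cow_keypoint_names <- function() {
  c("highest_back", "hook_A1", "aux_B1", "pin_A2", "aux_B2",
    "ischium_C1", "ischium_C2",
    "teat_left_top", "teat_left_bottom",
    "teat_right_top", "teat_right_bottom")
}

#' Construct a keypoint set
#'
#' @param names character vector of m unique labels.
#' @param points m x 3 coordinate matrix in meters.
#' @param index optional integer vector of point indices when the keypoints
#'   reference members of a specific cloud (an annotation).
#' @return an object of class `keypoint_set`.
#' @export
keypoint_set <- function(names, points, index = NULL) {
  names <- as.character(names)
  if (length(names) < 1) stop("a keypoint set needs at least one keypoint")
  if (anyDuplicated(names)) stop("keypoint names must be unique")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3 || nrow(points) != length(names))
    stop("'points' must be an m x 3 matrix matching 'names'")
  rownames(points) <- names
  if (!is.null(index)) {
    index <- as.integer(index)
    if (length(index) != length(names)) stop("'index' must match 'names'")
  }
  structure(list(names = names, points = points, index = index),
            class = "keypoint_set")
}

#' @rdname keypoint_set
#' @param x object to test.
#' @export
is_keypoint_set <- function(x) inherits(x, "keypoint_set")

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints%s\n", length(x$names),
              if (!is.null(x$index)) " (cloud-indexed)" else ""))
  print(round(x$points, 4))
  invisible(x)
}

#' Look up one keypoint by name
#' @param keypoints a [keypoint_set()].
#' @param name keypoint label.
#' @return length-3 coordinate vector.
#' @export
kp <- function(keypoints, name) {
  stopifnot(is_keypoint_set(keypoints))
  if (!name %in% keypoints$names)
    stop("keypoint '", name, "' missing from the set")
  keypoints$points[name, ]
}

#' Annotate a cloud by snapping keypoints to its members
#'
#' Each keypoint is replaced by the nearest cloud point, producing a valid
#' annotation (every annotated point is a cloud member, referenced by index).
#'
#' @param cloud a [point_cloud()].
#' @param keypoints a [keypoint_set()] with arbitrary coordinates.
#' @return a `keypoint_set` whose points are cloud members, with `index` set.
#' @export
snap_keypoints <- function(cloud, keypoints) {
  stopifnot(is_point_cloud(cloud), is_keypoint_set(keypoints))
  if (n_points(cloud) == 0) stop("cannot annotate an empty cloud")
  nn <- nn_search_cpp(keypoints$points, cloud$points)
  keypoint_set(keypoints$names, cloud$points[nn$idx, , drop = FALSE],
               index = nn$idx)
}

# check that an annotation's points are members of the cloud; returns indices
.annotation_index <- function(cloud, annotation) {
  pts <- cloud$points
  if (!is.null(annotation$index)) {
    idx <- annotation$index
    if (any(idx < 1 | idx > nrow(pts)))
      stop("annotation index out of range for this cloud")
    if (max(abs(pts[idx, , drop = FALSE] - annotation$points)) > 0)
      stop("annotation points do not match the indexed cloud members")
    return(idx)
  }
  nn <- nn_search_cpp(annotation$points, pts)
  if (any(nn$dist > 0))
    stop("annotated point is not a member of the cloud")
  nn$idx
}

#' Build the distance-field regression target
#'
#' Entry (i, j) is the Euclidean distance from cloud point i to annotated
#' keypoint j. Column j therefore attains 0 exactly at the annotated point.
#'
#' @param cloud a [point_cloud()] with n points.
#' @param annotation a [keypoint_set()] whose points are members of `cloud`.
#' @return an n x m numeric matrix with the keypoint names as columns.
#' @export
build_distance_field <- function(cloud, annotation) {
  stopifnot(is_point_cloud(cloud), is_keypoint_set(annotation))
  .annotation_index(cloud, annotation)
  pts <- cloud$points
  kpt <- annotation$points
  # direct per-column differences: exactly zero at the annotated point
  # (a gram-matrix formulation would leave ~1e-8 cancellation residue there)
  d <- vapply(seq_len(nrow(kpt)), function(j)
    sqrt((pts[, 1] - kpt[j, 1])^2 + (pts[, 2] - kpt[j, 2])^2 +
           (pts[, 3] - kpt[j, 3])^2), numeric(nrow(pts)))
  if (nrow(pts) == 1) d <- matrix(d, nrow = 1)
  colnames(d) <- annotation$names
  d
}

#' Extract keypoints from a distance field
#'
#' Keypoint j is the cloud point minimizing column j of the field; ties are
#' broken toward the lowest point index.
#'
#' @param cloud a [point_cloud()] with n points.
#' @param field n x m non-negative matrix (a [build_distance_field()] target
#'   or a model prediction).
#' @param names optional m labels (defaults to the field's column names).
#' @return a cloud-indexed `keypoint_set`.
#' @export
extract_keypoints <- function(cloud, field, names = colnames(field)) {
  stopifnot(is_point_cloud(cloud))
  if (n_points(cloud) == 0) stop("cannot extract keypoints from an empty cloud")
  field <- as.matrix(field)
  if (nrow(field) != n_points(cloud))
    stop("field rows must match the cloud size")
  if (is.null(names)) names <- paste0("kp", seq_len(ncol(field)))
  if (length(names) != ncol(field))
    stop("'names' must match the field columns")
  idx <- apply(field, 2, which.min)  # which.min takes the first minimum
  keypoint_set(names, cloud$points[idx, , drop = FALSE], index = idx)
}

#' Read/write a keypoint JSON sidecar
#'
#' The sidecar maps each keypoint name to its `[x, y, z]` position in meters.
#'
#' @param keypoints a [keypoint_set()].
#' @param path file path.
#' @return `read_keypoints_json` returns a `keypoint_set`;
#'   `write_keypoints_json` returns `path` invisibly.
#' @export
write_keypoints_json <- function(keypoints, path) {
  stopifnot(is_keypoint_set(keypoints))
  obj <- stats::setNames(lapply(seq_along(keypoints$names),
                                function(i) unname(keypoints$points[i, ])),
                         keypoints$names)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_keypoints_json
#' @export
read_keypoints_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keypoint_set(names(obj), do.call(rbind, obj))
}
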