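# The four conformation measurements and the 9-level linear scoring.
#
# stature height  M = d(highest_back, ground plane)
# rump angle      M = h1 - h2, the signed height difference between the hook
#                 (A1) and pin (A2) landmarks; despite the name this trait is
#                 recorded in cm, positive when the hook sits higher
# rump width      M = d(C1, C2), the inner ischium points on the transverse
#                 cross-section cut through A1 and B1
# front teat      M = (M_left + M_right) / 2, each teat measured top to
#                 bottom
#
# Each value is compared against a 9-row reference column; the score of the
# nearest reference value is assigned (ties round up, out-of-range values
# clamp to 1 or 9).

.score_tables <- list(
  stature = seq(128, 152, by = 3),
  rump_angle = seq(-4, 12, by = 2),
  rump_width = seq(5, 17, by = 1.5),
  teat_length = seq(2, 10, by = 1))

#' Reference table for one conformation trait
#'
#' Nine reference values (cm) paired with scores 1-9. Stature runs 128-152,
#' rump angle is encoded as the signed hook-above-pin offset -4..+12 (score s
#' at offset 2s - 6, so "hips level" scores 3), rump width 5-17 and front
#' teat length 2-10.
#'
#' @param trait one of `"stature"`, `"rump_angle"`, `"rump_width"`,
#'   `"teat_length"`.
#' @return data.frame with columns `value` (cm) and `score` (1-9).
#' @export
score_table <- function(trait = c("stature", "rump_angle", "rump_width",
                                  "teat_length")) {
  trait <- match.arg(trait)
  data.frame(value = .score_tables[[trait]], score = 1:9)
}

#' Map a measured value to its 1-9 conformation score
#'
#' Returns the score of the reference value nearest to `value_cm`. Values
#' beyond the extremes clamp to scores 1 and 9; an exact midpoint between two
#' rows rounds to the higher score.
#'
#' @param value_cm measured value in cm (vectorized).
#' @param trait trait name, see [score_table()].
#' @param table optional override: a data.frame with `value` and `score`
#'   columns (strictly increasing values).
#' @return integer score(s) in 1..9.
#' @examples
#' score_measurement(142.0, "stature")   # 6
#' score_measurement(6.06, "rump_angle") # 6
#' @export
score_measurement <- function(value_cm, trait = c("stature", "rump_angle",
                                                  "rump_width", "teat_length"),
                              table = NULL) {
  if (is.null(table)) table <- score_table(match.arg(trait))
  if (!all(c("value", "score") %in% names(table)))
    stop("score table needs 'value' and 'score' columns")
  if (is.unsorted(table$value, strictly = TRUE))
    stop("score table reference values must be strictly increasing")
  vapply(value_cm, function(v) {
    d <- abs(table$value - v)
    as.integer(max(table$score[d == min(d)]))  # midpoint ties take the higher score
  }, integer(1))
}

#' Measure stature height
#'
#' Vertical distance from the highest point of the back to the ground plane,
#' in cm.
#'
#' @param keypoints a [keypoint_set()] containing `highest_back`.
#' @param ground the ground [plane()].
#' @return stature in cm.
#' @export
measure_stature <- function(keypoints, ground) {
  100 * point_plane_distance(kp(keypoints, "highest_back"), ground)
}

#' Measure the rump angle (signed hook-pin height difference)
#'
#' `h1 - h2` in cm, where `h1` and `h2` are the point-to-ground-plane
#' distances of the hook landmark A1 and the pin landmark A2. Positive when
#' the hook sits higher than the pin.
#'
#' @param keypoints a [keypoint_set()] containing `hook_A1` and `pin_A2`.
#' @param ground the ground [plane()].
#' @return signed offset in cm.
#' @export
measure_rump_angle <- function(keypoints, ground) {
  h1 <- point_plane_distance(kp(keypoints, "hook_A1"), ground)
  h2 <- point_plane_distance(kp(keypoints, "pin_A2"), ground)
  100 * (h1 - h2)
}

#' Measure the rump width
#'
#' Cuts the cross-section slab of points within `slab_half_width` of the
#' vertical plane through the hook landmarks A1 and B1. When the ischium
#' keypoints C1/C2 are present they are used directly after checking they lie
#' inside the slab (snapping them to the nearest slab point when they do
#' not); otherwise the slab extrema along the transverse axis within the
#' ischium height band serve as a fallback. The cloud must be in the
#' canonical frame (z up, body axis along x).
#'
#' @param cloud the normalized body [point_cloud()].
#' @param keypoints a [keypoint_set()] with `hook_A1`, `aux_B1` and
#'   optionally `ischium_C1`, `ischium_C2`.
#' @param slab_half_width slab half-thickness in meters (default 0.015).
#' @return rump width in cm.
#' @export
measure_rump_width <- function(cloud, keypoints, slab_half_width = 0.015) {
  stopifnot(is_point_cloud(cloud))
  a1 <- kp(keypoints, "hook_A1")
  b1 <- kp(keypoints, "aux_B1")
  # vertical plane through A1 and B1: normal is horizontal, orthogonal to A1-B1
  dir <- b1[1:2] - a1[1:2]
  nd <- sqrt(sum(dir^2))
  nrm <- if (nd < 1e-9) c(1, 0, 0) else c(-dir[2], dir[1], 0) / nd
  cut <- plane(nrm, -sum(nrm * c(a1[1:2], 0)))
  sd <- point_plane_distance(cloud, cut)
  slab <- which(sd <= slab_half_width)
  if (length(slab) == 0) stop("rump-width cut produced an empty slab")
  has_c <- all(c("ischium_C1", "ischium_C2") %in% keypoints$names)
  if (has_c) {
    c1 <- kp(keypoints, "ischium_C1")
    c2 <- kp(keypoints, "ischium_C2")
    for (nm in c("c1", "c2")) {
      p <- get(nm)
      if (point_plane_distance(p, cut) > slab_half_width) {
        nn <- nn_search_cpp(matrix(p, 1), cloud$points[slab, , drop = FALSE])
        assign(nm, cloud$points[slab[nn$idx], ])
      }
    }
    100 * sqrt(sum((c1 - c2)^2))
  } else {
    # fallback: transverse extrema in the ischium height band of the slab
    pts <- cloud$points[slab, , drop = FALSE]
    zc <- stats::quantile(pts[, 3], 0.25, names = FALSE)
    band <- pts[abs(pts[, 3] - zc) <= 0.02, , drop = FALSE]
    if (nrow(band) < 2) band <- pts
    100 * (max(band[, 2]) - min(band[, 2]))
  }
}

#' Measure the front teat lengths
#'
#' Each teat is the Euclidean distance from its labelled top to its bottom;
#' the trait value is the mean of left and right.
#'
#' @param keypoints a [keypoint_set()] with `teat_left_top`,
#'   `teat_left_bottom`, `teat_right_top`, `teat_right_bottom`.
#' @return named vector `c(left, right, avg)` in cm.
#' @export
measure_teat_length <- function(keypoints) {
  left <- 100 * sqrt(sum((kp(keypoints, "teat_left_top") -
                          kp(keypoints, "teat_left_bottom"))^2))
  right <- 100 * sqrt(sum((kp(keypoints, "teat_right_top") -
                           kp(keypoints, "teat_right_bottom"))^2))
  c(left = left, right = right, avg = (left + right) / 2)
}

#' Full measurement report for one animal
#'
#' Runs the four measurements and scores each trait.
#'
#' @param cloud the normalized body [point_cloud()].
#' @param keypoints detected or ground-truth [keypoint_set()].
#' @param ground the ground [plane()].
#' @param slab_half_width passed to [measure_rump_width()].
#' @param tables optional named list of score-table overrides.
#' @return an object of class `measurement_report`.
#' @export
measure_cow <- function(cloud, keypoints, ground, slab_half_width = 0.015,
                        tables = NULL) {
  teat <- measure_teat_length(keypoints)
  vals <- list(
    stature_cm = unname(measure_stature(keypoints, ground)),
    rump_angle_cm = unname(measure_rump_angle(keypoints, ground)),
    rump_width_cm = unname(measure_rump_width(cloud, keypoints, slab_half_width)),
    teat_left_cm = unname(teat["left"]),
    teat_right_cm = unname(teat["right"]),
    teat_avg_cm = unname(teat["avg"]))
  tab <- function(tr) if (!is.null(tables)) tables[[tr]] else NULL
  scores <- c(
    stature = score_measurement(vals$stature_cm, "stature", tab("stature")),
    rump_angle = score_measurement(vals$rump_angle_cm, "rump_angle", tab("rump_angle")),
    rump_width = score_measurement(vals$rump_width_cm, "rump_width", tab("rump_width")),
    teat_length = score_measurement(vals$teat_avg_cm, "teat_length", tab("teat_length")))
  structure(c(vals, list(scores = scores)), class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report>\n")
  cat(sprintf("  stature height : %7.2f cm  (score %d)\n", x$stature_cm, x$scores["stature"]))
  cat(sprintf("  rump angle     : %7.2f cm  (score %d)\n", x$rump_angle_cm, x$scores["rump_angle"]))
  cat(sprintf("  rump width     : %7.2f cm  (score %d)\n", x$rump_width_cm, x$scores["rump_width"]))
  cat(sprintf("  front teats    : %.2f / %.2f, avg %.2f cm  (score %d)\n",
              x$teat_left_cm, x$teat_right_cm, x$teat_avg_cm, x$scores["teat_length"]))
  invisible(x)
}

#' Serialize a measurement report to/from JSON
#'
#' @param report a `measurement_report`.
#' @param path optional path; when given the JSON is written there.
#' @return `report_to_json` returns the JSON string (invisibly when `path`
#'   is given); `report_from_json` rebuilds the `measurement_report`.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    stature = list(value_cm = report$stature_cm, score = unname(report$scores["stature"])),
    rump_angle = list(value_cm = report$rump_angle_cm, score = unname(report$scores["rump_angle"])),
    rump_width = list(value_cm = report$rump_width_cm, score = unname(report$scores["rump_width"])),
    front_teat_length = list(value_cm = report$teat_avg_cm,
                             left_cm = report$teat_left_cm,
                             right_cm = report$teat_right_cm,
                             score = unname(report$scores["teat_length"])))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname report_to_json
#' @param json JSON string or file path.
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(
    stature_cm = obj$stature$value_cm,
    rump_angle_cm = obj$rump_angle$value_cm,
    rump_width_cm = obj$rump_width$value_cm,
    teat_left_cm = obj$front_teat_length$left_cm,
    teat_right_cm = obj$front_teat_length$right_cm,
    teat_avg_cm = obj$front_teat_length$value_cm,
    scores = c(stature = as.integer(obj$stature$score),
               rump_angle = as.integer(obj$rump_angle$score),
               rump_width = as.integer(obj$rump_width$score),
               teat_length = as.integer(obj$front_teat_length$score))),
    class = "measurement_report")
}

#' Overlay measurement markers on a cloud
#'
#' Returns the input cloud with colored marker points appended: one red
#' marker per keypoint plus sampled points along the measurement segments
#' (stature drop line, hook-pin pair, rump-width segment, teat segments).
#' The original points are carried over bit-identically, so the overlay is
#' non-destructive and viewable in any PLY viewer.
#'
#' @param cloud a [point_cloud()].
#' @param report a `measurement_report` (stored as the `report` attribute of
#'   the result, and the sidecar content).
#' @param keypoints the [keypoint_set()] the report was measured from.
#' @param spacing marker spacing along segments in meters (default 0.005).
#' @return a `point_cloud` with attributes `n_markers` (keypoint + segment
#'   sample count) and `report`.
#' @export
annotate_cloud <- function(cloud, report, keypoints, spacing = 0.005) {
  stopifnot(is_point_cloud(cloud), is_keypoint_set(keypoints))
  seg <- function(p, q) {
    n <- max(2L, ceiling(sqrt(sum((q - p)^2)) / spacing) + 1L)
    cbind(seq(p[1], q[1], length.out = n), seq(p[2], q[2], length.out = n),
          seq(p[3], q[3], length.out = n))
  }
  hb <- kp(keypoints, "highest_back")
  segs <- rbind(
    seg(hb, c(hb[1], hb[2], hb[3] - report$stature_cm / 100)),
    seg(kp(keypoints, "hook_A1"), kp(keypoints, "pin_A2")),
    seg(kp(keypoints, "ischium_C1"), kp(keypoints, "ischium_C2")),
    seg(kp(keypoints, "teat_left_top"), kp(keypoints, "teat_left_bottom")),
    seg(kp(keypoints, "teat_right_top"), kp(keypoints, "teat_right_bottom")))
  markers <- rbind(keypoints$points, segs)
  mcol <- rbind(matrix(rep(c(1, 0, 0), nrow(keypoints$points)), ncol = 3, byrow = TRUE),
                matrix(rep(c(0, 0.35, 1), nrow(segs)), ncol = 3, byrow = TRUE))
  base_col <- if (!is.null(cloud$colors)) cloud$colors
              else matrix(0.7, n_points(cloud), 3)
  out <- point_cloud(rbind(cloud$points, markers), colors = rbind(base_col, mcol))
  attr(out, "n_markers") <- nrow(markers)
  attr(out, "report") <- report
  out
}
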