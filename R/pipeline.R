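# End-to-end orchestration: acquire (synthetic or PLY) -> preprocess ->
# keypoints (trained model or ground-truth oracle) -> measure -> score ->
# annotate, with reproducible seeding and optional artifact output.

#' Run the full measurement pipeline
#'
#' Stages: acquire the scene (generate from a [cow_template()], read a PLY
#' path, or accept a `generate_scene()` result), optionally voxel-downsample,
#' extract and remove the ground and fence planes (RANSAC), remove
#' statistical outliers, normalize into the canonical frame, obtain keypoints
#' (trained model, or the ground-truth oracle for synthetic input), measure
#' the four traits and score them. Identical input and seed give an
#' identical report.
#'
#' @param input a `cow_template`, a scene list from [generate_scene()], or a
#'   PLY file path.
#' @param model optional fitted `keypoint_model`; required unless
#'   `oracle_keypoints = TRUE`.
#' @param oracle_keypoints use the generator's exact keypoints instead of a
#'   model (synthetic input only). Keeps the measurement stages testable
#'   independently of training stochasticity.
#' @param voxel optional voxel edge for initial downsampling (meters).
#' @param margin plane trim margin in meters.
#' @param dist_thresh,ransac_iters RANSAC parameters.
#' @param k_neighbors,std_ratio statistical outlier removal parameters.
#' @param slab_half_width rump-width slab half-thickness in meters.
#' @param tables optional score-table overrides (see [measure_cow()]).
#' @param seed integer seed for all stochastic stages.
#' @param out_dir optional directory; when given, the preprocessed cloud,
#'   the annotated cloud, the keypoints and the JSON report are written
#'   there.
#' @return list with `report` (a `measurement_report`), `cloud` (normalized
#'   body cloud), `keypoints`, `ground`/`fence` (fitted [plane()]s in the
#'   input frame), `transform` (input frame -> canonical frame), `truth`
#'   (when synthetic) and `artifacts` (paths, when `out_dir` given).
#' @export
run_pipeline <- function(input, model = NULL, oracle_keypoints = FALSE,
                         voxel = NULL, margin = 0.02, dist_thresh = 0.015,
                         ransac_iters = 1000, k_neighbors = 12,
                         std_ratio = 2.0, slab_half_width = 0.015,
                         tables = NULL, seed = 1L, out_dir = NULL) {
  stage <- "acquire"
  res <- tryCatch({
    truth <- NULL
    if (inherits(input, "cow_template")) {
      scene <- generate_scene(input)
      cloud <- scene$cloud; truth <- scene$truth
    } else if (is.character(input)) {
      cloud <- read_ply(input)
    } else if (is.list(input) && is_point_cloud(input$cloud)) {
      cloud <- input$cloud; truth <- input$truth
    } else stop("unsupported input")
    if (oracle_keypoints && is.null(truth))
      stop("oracle keypoints require synthetic input with ground truth")
    if (!oracle_keypoints && is.null(model))
      stop("a trained model is required unless oracle_keypoints = TRUE")

    stage <- "preprocess"
    body <- .extract_body(cloud, voxel = voxel, margin = margin,
                          dist_thresh = dist_thresh, n_iters = ransac_iters,
                          k_neighbors = k_neighbors, std_ratio = std_ratio,
                          seed = seed)
    norm <- normalize_coordinates(body$cloud, body$ground)
    ground0 <- plane(c(0, 0, 1), 0)

    stage <- "keypoints"
    kps <- if (oracle_keypoints) {
      keypoint_set(truth$keypoints$names,
                   apply_transform(truth$keypoints$points, norm$transform))
    } else detect_keypoints(model, norm$cloud)

    stage <- "measure"
    report <- measure_cow(norm$cloud, kps, ground0,
                          slab_half_width = slab_half_width, tables = tables)

    artifacts <- NULL
    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      artifacts <- c(
        body_ply = file.path(out_dir, "body_normalized.ply"),
        annotated_ply = file.path(out_dir, "annotated.ply"),
        keypoints_json = file.path(out_dir, "keypoints.json"),
        report_json = file.path(out_dir, "report.json"))
      write_ply(norm$cloud, artifacts[["body_ply"]])
      write_ply(annotate_cloud(norm$cloud, report, kps), artifacts[["annotated_ply"]])
      write_keypoints_json(kps, artifacts[["keypoints_json"]])
      report_to_json(report, artifacts[["report_json"]])
    }
    list(report = report, cloud = norm$cloud, keypoints = kps,
         ground = body$ground, fence = body$fence,
         transform = norm$transform, truth = truth, artifacts = artifacts)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Per-trait detection error table over a batch
#'
#' Mirrors the layout of repeatability tables in conformation studies: one
#' row per animal with the manual (reference) value, the automatic value and
#' their absolute error, plus the per-trait mean absolute error.
#'
#' @param reports list of `measurement_report` objects (the automatic
#'   measurements).
#' @param truths list of the same length: `cow_ground_truth` objects or
#'   named vectors with `stature_cm`, `rump_angle_cm`, `rump_width_cm`,
#'   `teat_avg_cm` (the reference measurements).
#' @return object of class `error_table`: list with `per_scene`
#'   (data.frame) and `mae` (named numeric, cm).
#' @export
evaluate_batch <- function(reports, truths) {
  if (length(reports) == 0) stop("'reports' must be non-empty")
  if (length(reports) != length(truths))
    stop("'reports' and 'truths' must have the same length")
  traits <- c("stature_cm", "rump_angle_cm", "rump_width_cm", "teat_avg_cm")
  getm <- function(x) {
    v <- if (inherits(x, "cow_ground_truth")) x$measurements
         else if (inherits(x, "measurement_report")) unlist(x[traits])
         else unlist(x)
    v[traits]
  }
  rows <- lapply(seq_along(reports), function(i) {
    auto <- getm(reports[[i]])
    man <- getm(truths[[i]])
    data.frame(scene = i,
               trait = sub("_cm$", "", traits),
               manual = unname(man), auto = unname(auto),
               error = unname(abs(man - auto)))
  })
  per_scene <- do.call(rbind, rows)
  mae <- tapply(per_scene$error, per_scene$trait, mean)
  mae <- stats::setNames(as.numeric(mae[sub("_cm$", "", traits)]),
                         sub("_cm$", "", traits))
  structure(list(per_scene = per_scene, mae = mae), class = "error_table")
}

#' @export
print.error_table <- function(x, ...) {
  for (tr in unique(x$per_scene$trait)) {
    d <- x$per_scene[x$per_scene$trait == tr, ]
    cat(sprintf("-- %s (cm) --\n", tr))
    cat(sprintf("  scene %2d: manual %8.2f  auto %8.2f  error %6.2f\n",
                d$scene, d$manual, d$auto, d$error), sep = "")
    cat(sprintf("  detection average error: %.2f\n", x$mae[[tr]]))
  }
  invisible(x)
}
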