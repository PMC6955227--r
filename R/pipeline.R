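# Five-stage pipeline: segmentation -> tracking -> pose -> features ->
# classification, plus the manifest-driven batch evaluation and the YAML
# config that exposes every tunable of the intermediate stages.

#' Default pipeline configuration
#'
#' All tunables of the pipeline in one list: threshold method and polarity,
#' calibration sampling, window size, frame step, morphology radii, KDE /
#' range parameters, regression and correlation flavours, and the
#' cross-validation protocol. The config round-trips losslessly through
#' YAML; unknown keys are rejected on read.
#'
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    threshold_method = "otsu",     # "otsu" or "fixed"
    threshold_value = NA,          # blue intensity for method = "fixed"
    polarity = "dark",             # animal darker ("dark") or lighter ("light")
    calibration_frames = 6L,       # frames sampled for the area calibration
    frame_step = 2L,               # process every n-th frame
    window_side = NA,              # fixed tracking window (px); NA = derived
    erosion_radius = NA,           # limb-removal radius (px); NA = derived
    dilation_radius = 2,           # joint-zone dilation radius (px)
    min_limb_area = 15,            # smallest limb component kept (px^2)
    kde_bandwidth = NA,            # range-feature KDE bandwidth; NA = Silverman
    gaussian_sigma = 1,            # post-KDE Gaussian convolution SD (cells)
    density_threshold_fraction = 0.05,
    correlation_method = "pearson",
    symmetry_intercept = FALSE,    # TRUE = regression with intercept
    standardize_features = TRUE,
    cv_folds = 10L,
    cv_repeats = 10L,
    seed = 1L
  ), class = "pipeline_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @param config a `pipeline_config` (for writing).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(vals)) base[[k]] <- if (is.null(vals[[k]])) NA else vals[[k]]
  base
}

cfg_or <- function(value, fallback) if (is.null(value) || all(is.na(value))) fallback else value

#' Run the full pipeline on one video
#'
#' Executes the five stages on a single video: area calibration,
#' frame-by-frame detection and tracking, pose and angle-pair recovery,
#' kinematic feature extraction with the joint-angle heatmap, and
#' (optionally) classification with a trained model. Frames where a stage
#' fails are marked invalid and skipped by the features, mirroring the
#' tolerant per-frame behaviour of the tracking stage.
#'
#' @param video a [frog_video] or a path to a PNG frame directory.
#' @param config a [default_config()] list.
#' @param classifier optional `froglet_classifier`; when missing the
#'   pipeline runs in features-only mode.
#' @param out_dir optional output directory; when given, writes
#'   `detections.csv`, `pose.csv`, `features.json` and `heatmap.png`.
#' @return list: `area_range`, `detections`, `poses` (data.frame),
#'   `features`, `histogram`, `predicted_label` (`NA` in features-only
#'   mode), `timings` (seconds per stage).
#' @export
run_pipeline <- function(video, config = default_config(), classifier = NULL,
                         out_dir = NULL) {
  if (is.character(video)) video <- video_from_dir(video)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  rng <- calibrate_area(video,
                        detector = threshold_roi_detector(
                          method = config$threshold_method,
                          fixed_value = cfg_or(config$threshold_value, NULL),
                          polarity = config$polarity),
                        n_frames = config$calibration_frames,
                        seed = config$seed,
                        method = config$threshold_method,
                        fixed_value = cfg_or(config$threshold_value, NULL),
                        polarity = config$polarity)
  timings["calibrate"] <- tic() - t0

  t0 <- tic()
  dets <- track_video(video, rng, frame_step = config$frame_step,
                      window_side = cfg_or(config$window_side,
                                           default_window_side(rng)),
                      method = config$threshold_method,
                      fixed_value = cfg_or(config$threshold_value, NULL),
                      polarity = config$polarity)
  timings["track"] <- tic() - t0
  if (!any(vapply(dets, `[[`, TRUE, "valid")))
    stop("no valid detections in the whole video")

  t0 <- tic()
  poses <- pose_video(dets,
                      erosion_radius = cfg_or(config$erosion_radius, NULL),
                      dilation_radius = config$dilation_radius,
                      min_limb_area = config$min_limb_area)
  timings["pose"] <- tic() - t0

  t0 <- tic()
  features <- extract_features(
    poses, poses = poses[poses$valid, , drop = FALSE],
    kde_bandwidth = cfg_or(config$kde_bandwidth, NULL),
    gaussian_sigma = config$gaussian_sigma,
    density_threshold_fraction = config$density_threshold_fraction)
  hist <- build_histogram(poses)
  timings["features"] <- tic() - t0

  label <- NA_character_
  if (!is.null(classifier)) {
    newrow <- data.frame(f1 = features$f1_synchronization,
                         f2 = features$f2_symmetry,
                         f3 = features$f3_range_right,
                         f4 = features$f4_range_left)
    names(newrow) <- classifier$feature_names[seq_len(ncol(newrow))]
    label <- as.character(predict(classifier, newrow))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(detections_table(dets),
                     file.path(out_dir, "detections.csv"), row.names = FALSE)
    utils::write.csv(poses, file.path(out_dir, "pose.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(f1_synchronization = features$f1_synchronization,
           f2_symmetry = features$f2_symmetry,
           f3_range_right = features$f3_range_right,
           f4_range_left = features$f4_range_left,
           n_valid_frames = features$n_valid_frames,
           missing = as.list(features$missing),
           predicted_label = label),
      file.path(out_dir, "features.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    write_heatmap_png(hist, file.path(out_dir, "heatmap.png"),
                      slope = features$f2_symmetry)
  }
  list(area_range = rng, detections = dets, poses = poses,
       features = features, histogram = hist, predicted_label = label,
       timings = timings)
}

#' Batch evaluation of classifiers and feature sets
#'
#' Given a labelled feature table (or a manifest of videos to process
#' first), runs repeated stratified cross-validation for every combination
#' of classifier and feature set and returns the comparison table (rows =
#' classifiers, one `mean`/`std` column pair per feature set).
#'
#' @param manifest data.frame with a `label` column and either feature
#'   columns `f1`..`f4` or a `path` column of frame directories to process
#'   through [run_pipeline()].
#' @param config a [default_config()].
#' @param classifiers classifier names, default all ten.
#' @param feature_sets named list of feature-column subsets.
#' @param out_csv optional path for the CSV table.
#' @return data.frame comparison table; the per-cell `cv_result` objects are
#'   attached as attribute `"results"`.
#' @export
batch_evaluate <- function(manifest, config = default_config(),
                           classifiers = classifier_kinds(),
                           feature_sets = list("f1-f2" = c("f1", "f2"),
                                               "f3-f4" = c("f3", "f4"),
                                               "all" = c("f1", "f2", "f3", "f4")),
                           out_csv = NULL) {
  if (is.null(manifest$label)) stop("manifest must carry a 'label' column")
  if (!all(c("f1", "f2", "f3", "f4") %in% names(manifest))) {
    if (is.null(manifest$path)) stop("manifest needs features f1..f4 or a 'path' column")
    feats <- lapply(manifest$path, function(p) {
      res <- run_pipeline(p, config)
      data.frame(f1 = res$features$f1_synchronization,
                 f2 = res$features$f2_symmetry,
                 f3 = res$features$f3_range_right,
                 f4 = res$features$f4_range_left)
    })
    manifest <- cbind(manifest, do.call(rbind, feats))
  }
  if (length(unique(manifest$label)) < 2) stop("at least two classes required")
  tab <- data.frame(classifier = classifiers)
  results <- list()
  for (fs in names(feature_sets)) {
    ds <- feature_dataset(manifest[, feature_sets[[fs]], drop = FALSE],
                          manifest$label)
    cv <- lapply(classifiers, function(k)
      cross_validate(ds, k, n_folds = config$cv_folds,
                     n_repeats = config$cv_repeats, seed = config$seed,
                     standardize = config$standardize_features))
    results[[fs]] <- cv
    tab[[paste0(fs, "_mean")]] <- vapply(cv, `[[`, 1, "mean_accuracy")
    tab[[paste0(fs, "_std")]] <- vapply(cv, `[[`, 1, "std_accuracy")
  }
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  attr(tab, "results") <- results
  tab
}
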