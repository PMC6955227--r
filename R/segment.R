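#' Blue-channel thresholding
#'
#' Separates the dark animal from the light background using the blue
#' channel, the channel with the largest froglet/background contrast in
#' dorsal-view recordings. With `method = "otsu"` the threshold is chosen by
#' Otsu's criterion on the blue histogram; `method = "fixed"` uses
#' `fixed_value`.
#'
#' @param frame RGB array `H x W x 3`.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value blue intensity in `[0, 1]`; required for `"fixed"`.
#' @param polarity `"dark"` (default; animal darker than background) or
#'   `"light"`. With `"dark"`, a thresholded foreground covering more than
#'   half the frame is treated as a polarity violation and raises an error.
#' @return logical matrix, `TRUE` on the animal. If the frame is (near)
#'   uniform the mask is empty and carries `attr(, "degenerate") = TRUE`.
#' @export
threshold_blue <- function(frame, method = c("otsu", "fixed"),
                           fixed_value = NULL, polarity = c("dark", "light")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stop("frame must have three colour channels")
  blue <- frame[, , 3]
  if (max(blue) - min(blue) < 1e-3) {
    mask <- matrix(FALSE, nrow(blue), ncol(blue))
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  thr <- switch(method,
    otsu = EBImage::otsu(blue, range = range(blue)),
    fixed = {
      if (is.null(fixed_value)) stop("method 'fixed' requires fixed_value")
      fixed_value
    })
  mask <- if (polarity == "dark") blue < thr else blue > thr
  if (mean(mask) > 0.5)
    stop("thresholded foreground covers most of the frame; ",
         "check the polarity setting (animal assumed ",
         if (polarity == "dark") "darker" else "lighter",
         " than the background)")
  attr(mask, "threshold") <- thr
  mask
}

#' Animal area acceptance range
#'
#' @param calibration_area calibration area, pixels^2.
#' @return list with `calibration_area`, `lower_bound = 0.9 x`,
#'   `upper_bound = 1.1 x`.
#' @export
area_range <- function(calibration_area) {
  stopifnot(calibration_area > 0)
  structure(list(calibration_area = calibration_area,
                 lower_bound = 0.9 * calibration_area,
                 upper_bound = 1.1 * calibration_area),
            class = "area_range")
}

#' @export
print.area_range <- function(x, ...) {
  cat(sprintf("<area_range> calibration %.1f px^2, accept [%.1f, %.1f]\n",
              x$calibration_area, x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Default region-of-interest detector
#'
#' The pluggable ROI-detector contract is `function(frame) -> c(x0, y0, x1,
#' y1)` bounding box or `NULL` when no animal is found. The default detector
#' thresholds the whole frame and returns the bounding box of the largest
#' connected component, padded by `pad` pixels. Users with a learned
#' detector (e.g. a trained network) can supply any function honouring the
#' same contract.
#'
#' @inheritParams threshold_blue
#' @param pad padding around the component bounding box, pixels.
#' @return a detector function.
#' @export
threshold_roi_detector <- function(method = "otsu", fixed_value = NULL,
                                   polarity = "dark", pad = 10) {
  function(frame) {
    mask <- threshold_blue(frame, method, fixed_value, polarity)
    if (isTRUE(attr(mask, "degenerate")) || !any(mask)) return(NULL)
    labels <- label_components(mask)
    st <- component_stats(labels)
    big <- st$label[which.max(st$area)]
    idx <- which(labels == big)
    rc <- arrayInd(idx, dim(labels))
    c(max(1, min(rc[, 2]) - pad), max(1, min(rc[, 1]) - pad),
      min(ncol(mask), max(rc[, 2]) + pad), min(nrow(mask), max(rc[, 1]) + pad))
  }
}

#' Calibrate the animal's pixel area
#'
#' Samples `n_frames` random frames (seeded), measures the thresholded
#' animal area inside the detector-proposed region of each, and returns the
#' median area with a +/-10% acceptance band. The median makes the estimate
#' robust to the occasional frame where the detector latches onto another
#' object.
#'
#' @param video a [frog_video].
#' @param detector an ROI detector, see [threshold_roi_detector()].
#' @param n_frames number of frames to sample (default 6).
#' @param seed integer seed for the frame draw.
#' @inheritParams threshold_blue
#' @return an [area_range()].
#' @export
calibrate_area <- function(video, detector = threshold_roi_detector(),
                           n_frames = 6, seed = 1,
                           method = "otsu", fixed_value = NULL,
                           polarity = "dark") {
  stopifnot(n_frames(video) >= n_frames)
  picks <- withr::with_seed(seed, sample.int(n_frames(video), n_frames))
  areas <- numeric(0)
  for (i in picks) {
    frame <- get_frame(video, i)
    box <- detector(frame)
    if (is.null(box)) next
    sub <- frame[box[2]:box[4], box[1]:box[3], , drop = FALSE]
    mask <- threshold_blue(sub, method, fixed_value, polarity)
    if (isTRUE(attr(mask, "degenerate")) || !any(mask)) next
    st <- component_stats(label_components(mask))
    areas <- c(areas, max(st$area))
  }
  if (length(areas) == 0) stop("no animal found in any sampled frame")
  area_range(stats::median(areas))
}

new_detection <- function(frame_index, valid, mask = NULL, window_origin = c(NA, NA),
                          centroid = c(NA, NA), area = NA_real_) {
  structure(list(frame_index = frame_index, valid = valid, mask = mask,
                 window_origin = window_origin, centroid = centroid,
                 area = area),
            class = "froglet_detection")
}

default_window_side <- function(range) {
  side <- 2 * 2 * sqrt(range$calibration_area / pi)  # 2x the bounding square
  s <- as.integer(ceiling(side))
  if (s %% 2 == 0) s + 1L else s
}

crop_window <- function(frame, centre, side) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  half <- side %/% 2
  x0 <- round(centre[1]) - half; y0 <- round(centre[2]) - half
  x0 <- max(1, min(x0, w - side + 1)); y0 <- max(1, min(y0, h - side + 1))
  x1 <- min(w, x0 + side - 1); y1 <- min(h, y0 + side - 1)
  list(sub = frame[y0:y1, x0:x1, , drop = FALSE], origin = c(x0, y0))
}

#' Detect the froglet in one frame
#'
#' Thresholds the frame (restricted to the fixed-size window carried over
#' from the previous detection, when available), filters connected
#' components to those whose area lies in the +/-10% calibration band, and
#' among the survivors picks the one whose centroid is closest to the
#' previous detection (ties broken by lower component label; largest
#' survivor when there is no previous detection). When nothing survives, an
#' invalid detection is returned that carries the previous window forward so
#' tracking can re-acquire.
#'
#' @param frame RGB array.
#' @param range an [area_range()].
#' @param prev previous detection or `NULL`.
#' @param frame_index index recorded on the detection.
#' @param window_side odd window size in pixels; default derived from the
#'   calibration area (twice the side of the square bounding the
#'   calibration-area disc).
#' @inheritParams threshold_blue
#' @return a `froglet_detection`: `frame_index`, `valid`, windowed logical
#'   `mask`, `window_origin` (x, y of the window's top-left pixel in the full
#'   frame), full-frame `centroid`, `area`.
#' @export
detect_froglet <- function(frame, range, prev = NULL, frame_index = 1L,
                           window_side = default_window_side(range),
                           method = "otsu", fixed_value = NULL,
                           polarity = "dark") {
  have_prev <- !is.null(prev) && !anyNA(prev$window_origin)
  if (have_prev) {
    prev_centre <- if (prev$valid) prev$centroid else
      prev$window_origin + (window_side - 1) / 2
    win <- crop_window(frame, prev_centre, window_side)
  } else {
    win <- list(sub = frame, origin = c(1, 1))
  }
  mask <- threshold_blue(win$sub, method, fixed_value, polarity)
  fail <- function() new_detection(frame_index, FALSE,
                                   window_origin = if (have_prev) prev$window_origin else c(NA, NA))
  if (isTRUE(attr(mask, "degenerate")) || !any(mask)) return(fail())
  labels <- label_components(mask)
  st <- component_stats(labels)
  st <- st[st$area >= range$lower_bound & st$area <= range$upper_bound, , drop = FALSE]
  if (nrow(st) == 0) return(fail())
  if (have_prev && prev$valid) {
    gx <- st$cx + win$origin[1] - 1; gy <- st$cy + win$origin[2] - 1
    d <- sqrt((gx - prev$centroid[1])^2 + (gy - prev$centroid[2])^2)
    pick <- st$label[order(d, st$label)[1]]
  } else {
    pick <- st$label[order(-st$area, st$label)[1]]
  }
  row <- st[st$label == pick, ]
  centroid <- c(row$cx + win$origin[1] - 1, row$cy + win$origin[2] - 1)
  # re-crop a window centred on the chosen detection
  final <- crop_window(frame, centroid, min(window_side, dim(frame)[1], dim(frame)[2]))
  fmask <- threshold_blue(final$sub, method, fixed_value, polarity)
  flab <- label_components(fmask)
  lx <- round(centroid[1]) - final$origin[1] + 1
  ly <- round(centroid[2]) - final$origin[2] + 1
  lx <- max(1, min(lx, ncol(flab))); ly <- max(1, min(ly, nrow(flab)))
  keep <- flab[ly, lx]
  if (keep == 0) {
    st2 <- component_stats(flab)
    d2 <- sqrt((st2$cx - lx)^2 + (st2$cy - ly)^2)
    keep <- st2$label[which.min(d2)]
  }
  new_detection(frame_index, TRUE, mask = flab == keep,
                window_origin = final$origin, centroid = centroid,
                area = row$area)
}

#' Track the froglet through a video
#'
#' Runs [detect_froglet()] on every `frame_step`-th frame (the stock setting
#' processes one frame in two), feeding each detection forward as the
#' previous-frame reference of the next.
#'
#' @inheritParams detect_froglet
#' @param video a [frog_video].
#' @param frame_step process every `frame_step`-th frame (>= 1).
#' @return list of `froglet_detection` objects for frames
#'   `1, 1 + frame_step, ...` (`ceiling(n_frames / frame_step)` of them).
#' @export
track_video <- function(video, range, frame_step = 2L,
                        window_side = default_window_side(range),
                        method = "otsu", fixed_value = NULL,
                        polarity = "dark") {
  stopifnot(frame_step >= 1)
  idx <- seq(1L, n_frames(video), by = frame_step)
  out <- vector("list", length(idx))
  prev <- NULL
  for (k in seq_along(idx)) {
    det <- detect_froglet(get_frame(video, idx[k]), range, prev,
                          frame_index = idx[k], window_side = window_side,
                          method = method, fixed_value = fixed_value,
                          polarity = polarity)
    out[[k]] <- det
    prev <- det
  }
  out
}

#' Tabulate detections
#' @param detections list from [track_video()].
#' @return data.frame with columns `frame_index`, `valid`, `cx`, `cy`,
#'   `area`, `window_x`, `window_y`.
#' @export
detections_table <- function(detections) {
  data.frame(frame_index = vapply(detections, `[[`, 1, "frame_index"),
             valid = vapply(detections, `[[`, TRUE, "valid"),
             cx = vapply(detections, function(d) d$centroid[1], 1),
             cy = vapply(detections, function(d) d$centroid[2], 1),
             area = vapply(detections, `[[`, 1, "area"),
             window_x = vapply(detections, function(d) d$window_origin[1], 1),
             window_y = vapply(detections, function(d) d$window_origin[2], 1))
}
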