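# Kinematic summaries of an angle-pair sequence: the 180 x 180 joint-angle
# histogram and the four features F1 (synchronization), F2 (symmetry),
# F3/F4 (right/left hindfoot angular range).

valid_pairs <- function(pairs) {
  ok <- stats::complete.cases(pairs$alpha_right, pairs$alpha_left)
  if (!is.null(pairs$valid)) ok <- ok & pairs$valid
  pairs[ok, , drop = FALSE]
}

#' Build the 2D joint-angle histogram
#'
#' Counts how many frames of the video have the hindfeet at each angle-pair,
#' on a 180 x 180 grid at 1 deg x 1 deg resolution. Bin `b` covers
#' `[b, b + 1)` degrees; row index is the right-foot bin, column the left.
#' Angles of exactly 180 deg are clamped to bin 179; invalid pairs are
#' skipped.
#'
#' @param pairs data.frame with columns `alpha_right`, `alpha_left` and
#'   optionally `valid`.
#' @return 180 x 180 integer matrix of class `angle_histogram`.
#' @export
build_histogram <- function(pairs) {
  p <- valid_pairs(pairs)
  br <- pmin(floor(p$alpha_right), 179)
  bl <- pmin(floor(p$alpha_left), 179)
  counts <- tabulate(br + 180 * bl + 1, nbins = 180 * 180)
  m <- matrix(as.integer(counts), 180, 180)
  class(m) <- c("angle_histogram", class(m))
  m
}

#' Min-max normalize a histogram for heatmap display
#'
#' Rescales the counts to `[0, 1]` as `(c - min) / (max - min)`; a histogram
#' with all bins equal (including all-zero) maps to all zeros.
#'
#' @param hist matrix from [build_histogram()].
#' @export
normalize_heatmap <- function(hist) {
  lo <- min(hist); hi <- max(hist)
  if (hi == lo) return(matrix(0, nrow(hist), ncol(hist)))
  (unclass(hist) - lo) / (hi - lo)
}

#' F1: hindfoot synchronization
#'
#' The correlation between the right and left hindfoot angle traces.
#' Values near +1 indicate synchronized strokes, near -1 inverted movement
#' (one foot forward while the other moves back), and near 0 independent
#' movement of the two feet.
#'
#' @inheritParams build_histogram
#' @param method correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @return correlation in `[-1, 1]`.
#' @export
synchronization <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  p <- valid_pairs(pairs)
  if (nrow(p) < 2) stop("synchronization undefined: fewer than 2 valid angle-pairs")
  if (stats::sd(p$alpha_right) == 0 || stats::sd(p$alpha_left) == 0)
    stop("synchronization undefined: an angle trace has zero variance")
  stats::cor(p$alpha_right, p$alpha_left, method = method)
}

#' F2: stroke symmetry
#'
#' The slope of a first-order linear regression of the right hindfoot angle
#' on the left. With the default through-origin fit the slope is
#' `sum(aR * aL) / sum(aL^2)`: 1 when both feet make equal strokes, 0.5 when
#' the right foot covers half the left foot's arc.
#'
#' @inheritParams build_histogram
#' @param intercept if `TRUE`, fit an ordinary regression with intercept and
#'   report its slope instead of the through-origin slope.
#' @return the symmetry coefficient (slope).
#' @export
symmetry <- function(pairs, intercept = FALSE) {
  p <- valid_pairs(pairs)
  if (nrow(p) < 2) stop("symmetry undefined: fewer than 2 valid angle-pairs")
  if (all(p$alpha_left == 0)) stop("symmetry undefined: left trace identically zero")
  if (intercept) {
    unname(stats::coef(stats::lm(alpha_right ~ alpha_left, data = p))[2])
  } else {
    sum(p$alpha_right * p$alpha_left) / sum(p$alpha_left^2)
  }
}

#' F3/F4: angular range of motion of one hindfoot
#'
#' Smooths the cloud of foot positions with a bivariate kernel density
#' estimate followed by a Gaussian convolution, thresholds the smoothed
#' density at a fraction of its maximum, and returns the arc (in degrees,
#' at the body centre) subtended between the extreme angles of the surviving
#' region.
#'
#' @param foot_positions matrix/data.frame with columns `x`, `y`: foot
#'   positions in the oriented body frame (x lateral, y posterior).
#' @param centroid angle vertex, default the body centre `c(0, 0)` of
#'   centroid-relative positions.
#' @param kde_bandwidth KDE bandwidth (passed to [MASS::kde2d()]'s `h`,
#'   which uses kernel SD `h/4`); default Silverman's rule per axis with a
#'   floor of 2 px.
#' @param gaussian_sigma SD of the post-KDE Gaussian convolution, grid cells.
#' @param density_threshold_fraction threshold as a fraction of the density
#'   maximum.
#' @param grid_resolution density grid spacing, pixels.
#' @return angular range, degrees.
#' @export
foot_range <- function(foot_positions, centroid = c(0, 0),
                       kde_bandwidth = NULL, gaussian_sigma = 1,
                       density_threshold_fraction = 0.05,
                       grid_resolution = 1) {
  pos <- as.matrix(as.data.frame(foot_positions)[, c("x", "y")])
  pos <- pos[stats::complete.cases(pos), , drop = FALSE]
  if (nrow(pos) < 1) stop("at least one valid foot position required")
  if (is.null(kde_bandwidth)) {
    bw <- function(v) if (length(v) > 1 && stats::sd(v) > 0)
      MASS::bandwidth.nrd(v) else 0
    kde_bandwidth <- pmax(c(bw(pos[, 1]), bw(pos[, 2])), 2)
  }
  kde_bandwidth <- rep_len(pmax(kde_bandwidth, 1e-6), 2)
  pad <- max(kde_bandwidth) + 3 * gaussian_sigma * grid_resolution
  lims <- c(min(pos[, 1]) - pad, max(pos[, 1]) + pad,
            min(pos[, 2]) - pad, max(pos[, 2]) + pad)
  n <- c(ceiling((lims[2] - lims[1]) / grid_resolution),
         ceiling((lims[4] - lims[3]) / grid_resolution)) + 1
  kd <- MASS::kde2d(pos[, 1], pos[, 2], h = kde_bandwidth, n = n, lims = lims)
  dens <- convolve2d(kd$z, gaussian_kernel2d(gaussian_sigma))
  keep <- which(dens >= density_threshold_fraction * max(dens), arr.ind = TRUE)
  if (nrow(keep) == 0) stop("empty region of movement: density threshold too high")
  gx <- kd$x[keep[, 1]] - centroid[1]
  gy <- kd$y[keep[, 2]] - centroid[2]
  ang <- sort(atan2(gy, gx) * 180 / pi)
  if (length(ang) == 1) return(0)
  # arc subtended by the region, measured circularly so that the branch cut
  # of atan2 (relevant for the left foot, which lives around +/-180 deg)
  # cannot inflate the range
  gaps <- c(diff(ang), ang[1] + 360 - ang[length(ang)])
  360 - max(gaps)
}

#' Convert hindfoot angles to body-frame positions
#'
#' Inverse of the angle convention: places a foot at `radius` pixels from
#' the body centre at the given angle, on the requested side.
#'
#' @param alpha angles in degrees.
#' @param side `"right"` or `"left"`.
#' @param radius centroid-to-foot distance, pixels.
#' @return data.frame with columns `x`, `y` (centroid-relative).
#' @export
angles_to_positions <- function(alpha, side = c("right", "left"), radius = 58) {
  side <- match.arg(side)
  sgn <- if (side == "right") 1 else -1
  data.frame(x = sgn * radius * cos(alpha * pi / 180),
             y = radius * sin(alpha * pi / 180))
}

#' Assemble the four kinematic features
#'
#' @param pairs angle-pair table (e.g. from [pose_video()] or ground-truth
#'   traces renamed to `alpha_right`/`alpha_left`).
#' @param poses optional pose table from [pose_video()]; when supplied, the
#'   range features use the recovered hindfoot positions, otherwise foot
#'   positions are reconstructed from the angles at `radius`.
#' @param radius centroid-to-foot distance used for the reconstruction.
#' @param ... passed to [foot_range()].
#' @return list of class `kinematic_features`: `f1_synchronization`,
#'   `f2_symmetry`, `f3_range_right`, `f4_range_left`, `n_valid_frames`,
#'   and a logical `missing` flag per feature (a feature whose computation
#'   is undefined, e.g. a zero-variance trace, is reported as `NA` and
#'   flagged rather than silently zeroed).
#' @export
extract_features <- function(pairs, poses = NULL, radius = 58, ...) {
  p <- valid_pairs(pairs)
  grab <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  f1 <- grab(synchronization(pairs))
  f2 <- grab(symmetry(pairs))
  if (!is.null(poses)) {
    right <- data.frame(x = poses$hind_right_x, y = poses$hind_right_y)
    left <- data.frame(x = poses$hind_left_x, y = poses$hind_left_y)
  } else {
    right <- angles_to_positions(p$alpha_right, "right", radius)
    left <- angles_to_positions(p$alpha_left, "left", radius)
  }
  f3 <- grab(foot_range(right, ...))
  f4 <- grab(foot_range(left, ...))
  structure(list(f1_synchronization = f1, f2_symmetry = f2,
                 f3_range_right = f3, f4_range_left = f4,
                 n_valid_frames = nrow(p),
                 missing = c(f1 = is.na(f1), f2 = is.na(f2),
                             f3 = is.na(f3), f4 = is.na(f4))),
            class = "kinematic_features")
}

#' @export
print.kinematic_features <- function(x, ...) {
  cat(sprintf(paste0("<kinematic_features> F1 sync %.3f | F2 symmetry %.3f | ",
                     "F3 range R %.1f deg | F4 range L %.1f deg (%d frames)\n"),
              x$f1_synchronization, x$f2_symmetry, x$f3_range_right,
              x$f4_range_left, x$n_valid_frames))
  invisible(x)
}

#' Write the joint-angle heatmap as a PNG
#'
#' Renders the min-max normalized histogram with a blue (never observed) to
#' red (most common angle-pair) colour scale, the white identity diagonal
#' (perfect mirror symmetry) and, optionally, a black line of the fitted
#' symmetry slope. The image origin is the lower-left corner (small angles
#' bottom-left); the left-foot angle runs along x and the right-foot angle
#' along y.
#'
#' @param hist matrix from [build_histogram()].
#' @param path output PNG path.
#' @param slope optional symmetry slope to overlay.
#' @param scale integer pixel upscaling of the 180 x 180 grid.
#' @export
write_heatmap_png <- function(hist, path, slope = NULL, scale = 2L) {
  norm <- normalize_heatmap(hist)
  ramp <- grDevices::colorRamp(c("#2166ac", "#67a9cf", "#f7f7f7",
                                 "#ef8a62", "#b2182b"))
  rgbv <- ramp(as.vector(norm)) / 255
  img <- array(0, c(180, 180, 3))
  for (k in 1:3) img[, , k] <- matrix(rgbv[, k], 180, 180)
  paint <- function(r_bin, c_bin, col) {
    ok <- r_bin >= 1 & r_bin <= 180 & c_bin >= 1 & c_bin <= 180
    for (k in 1:3) img[cbind(r_bin[ok], c_bin[ok], k)] <<- col[k]
  }
  paint(1:180, 1:180, c(1, 1, 1))                      # identity diagonal
  if (!is.null(slope) && is.finite(slope))
    paint(round(slope * (1:180)), 1:180, c(0, 0, 0))   # fitted slope line
  big <- img[rep(180:1, each = scale), rep(1:180, each = scale), ]  # y up
  png::writePNG(big, target = path)
  invisible(path)
}
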