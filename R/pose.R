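# Pose recovery: orient each body mask head-up, isolate the limbs, find the
# skeleton endpoints and turn the two hindfeet into the per-frame angle-pair.
#
# Angle convention (also used by the renderer and the features): in the
# oriented, head-up frame with the image row index growing downward,
#   alpha_R = atan2(dy, dx)   for the right hindfoot at offset (dx, dy) from
#                             the body centre (0 = straight lateral right,
#                             90 = straight posterior),
#   alpha_L = atan2(dy, -dx)  the mirror construction on the left,
# so a mirror-symmetric posture yields alpha_R == alpha_L.

default_erosion_radius <- function(mask) {
  # quarter of the body semi-minor axis, estimated from the mask area under
  # a 2:1 ellipse aspect: area = pi * (2b) * b  =>  b = sqrt(area / (2 pi))
  max(3L, as.integer(round(0.25 * sqrt(sum(mask > 0) / (2 * pi)))))
}

#' Estimate the body-axis orientation
#'
#' Erodes the mask until the limbs vanish, then fits the principal axis of
#' the remaining body region.
#'
#' @param mask logical/0-1 matrix (animal = TRUE).
#' @param erosion_radius disc radius in pixels; default is a quarter of the
#'   body semi-minor axis estimated from the mask area.
#' @return angle of the body axis versus horizontal, degrees in `(-90, 90]`
#'   (90 = vertical axis), measured in screen coordinates.
#' @export
estimate_orientation <- function(mask, erosion_radius = default_erosion_radius(mask)) {
  body <- mask_erode(mask, erosion_radius)
  if (!any(body > 0)) stop("mask empty after erosion; erosion_radius too large")
  ang <- principal_axis(body)
  if (attr(ang, "axis_ratio") < 1.15)
    stop("degenerate orientation: region is nearly isotropic (no principal axis)")
  as.numeric(ang)
}

#' Rotate a mask head-up
#'
#' Rotates the mask so the body axis is vertical, then resolves the 180-deg
#' ambiguity by pixel counting: if the half above the midline holds strictly
#' more foreground than the half below, the mask is rotated a further
#' 180 deg. The posterior half (hindlimbs plus pelvis) is the heavier half
#' and must end up at the bottom; ties do not flip. The midline is the
#' centroid row of the limb-free (opened) body: splitting at the full-mask
#' centroid would bias the count toward the lighter half, because the heavy
#' hindlimb mass drags that centroid posteriorly.
#'
#' @inheritParams estimate_orientation
#' @param angle body-axis angle from [estimate_orientation()], degrees.
#' @return logical mask on an expanded square canvas, head up, with
#'   attribute `"rotation"` = total rotation applied (degrees).
#' @export
normalize_orientation <- function(mask, angle,
                                  erosion_radius = default_erosion_radius(mask)) {
  stopifnot(is.finite(angle))
  rho <- 90 - angle
  rot <- rotate_mask(mask, rho)
  body <- mask_open(rot, erosion_radius)
  cy <- if (any(body > 0)) mask_centroid(body)["y"] else mask_centroid(rot)["y"]
  rows <- which(rot, arr.ind = TRUE)[, 1]
  if (sum(rows < cy) > sum(rows > cy)) {
    rot <- rot[nrow(rot):1, ncol(rot):1]   # exact 180-deg rotation
    rho <- rho + 180
  }
  attr(rot, "rotation") <- rho
  rot
}

#' Extract limbs and joint zones
#'
#' Reconstructs the limb-free body by a morphological opening (erosion
#' followed by dilation, which removes any protrusion thinner than about
#' twice the radius while restoring the body outline), takes the set
#' difference `mask - body` as the limb mask, and intersects the dilated
#' limbs with the dilated body to delimit the joint zones where each limb
#' attaches.
#'
#' @inheritParams estimate_orientation
#' @param oriented_mask head-up mask from [normalize_orientation()].
#' @param dilation_radius disc radius for the joint-zone dilation, pixels.
#' @param min_limb_area components smaller than this are discarded as
#'   boundary slivers, pixels^2.
#' @return list: `limb_mask` (labelled limb components), `joint_mask`
#'   (labelled joint zones), `body` (logical body mask), `n_limbs`.
#' @export
extract_limbs <- function(oriented_mask,
                          erosion_radius = default_erosion_radius(oriented_mask),
                          dilation_radius = 2, min_limb_area = 15) {
  if (!any(oriented_mask > 0)) stop("empty mask")
  body <- mask_open(oriented_mask, erosion_radius) > 0.5
  limbs <- (oriented_mask > 0.5) & !body
  labels <- label_components(limbs)
  st <- component_stats(labels)
  keep <- st$label[st$area >= min_limb_area]
  if (length(keep) == 0) stop("no limb components found")
  limbs <- matrix(labels %in% keep, nrow(labels))
  limb_labels <- label_components(limbs)
  joints <- (mask_dilate(limbs, dilation_radius) > 0.5) &
            (mask_dilate(body, dilation_radius) > 0.5)
  list(limb_mask = limb_labels, joint_mask = label_components(joints),
       body = body, n_limbs = max(limb_labels))
}

#' Skeleton endpoints
#'
#' Thins the limb mask to its 1-pixel morphological skeleton (Zhang-Suen)
#' and returns the skeleton pixels with exactly one 8-connected skeleton
#' neighbour - the candidate hands and feet.
#'
#' @param limb_mask logical/labelled matrix of limb pixels.
#' @return matrix with columns `x`, `y`, one row per endpoint.
#' @export
skeleton_endpoints <- function(limb_mask) {
  m <- as_mask(limb_mask)
  if (!any(m > 0)) stop("empty mask")
  skel <- thin_mask(m)
  nb <- neighbor_count(skel)
  idx <- which(skel > 0 & (nb == 1 | nb == 0))
  rc <- arrayInd(idx, dim(skel))
  cbind(x = rc[, 2], y = rc[, 1])
}

quadrant_of <- function(x, y, cx, cy) {
  side <- ifelse(x > cx, "right", ifelse(x < cx, "left", "right"))
  half <- ifelse(y > cy, "hind", "fore")
  paste(half, side, sep = "_")
}

#' Assign skeleton endpoints to limbs
#'
#' Splits the oriented frame into four quadrants around the body centre (one
#' per limb) and, within each quadrant, keeps the endpoint farthest from
#' that quadrant's joint zone. Quadrants without any endpoint yield an
#' invalid limb.
#'
#' @param endpoints matrix from [skeleton_endpoints()].
#' @param joint_zones labelled joint-zone matrix (from [extract_limbs()]).
#' @param centroid body centre `c(x, y)` in the oriented frame.
#' @param frame_index recorded on the pose.
#' @param orientation recorded on the pose, degrees.
#' @return a `froglet_pose`: `centroid`, `orientation`, `endpoints` (list of
#'   four `c(x, y)` offsets RELATIVE to the centroid, named `fore_right`,
#'   `fore_left`, `hind_right`, `hind_left`) and `valid_limbs`.
#' @export
assign_limbs <- function(endpoints, joint_zones, centroid,
                         frame_index = NA_integer_, orientation = NA_real_) {
  if (is.null(nrow(endpoints)) || nrow(endpoints) == 0)
    stop("at least one endpoint required")
  limbs <- c("fore_right", "fore_left", "hind_right", "hind_left")
  epq <- quadrant_of(endpoints[, "x"], endpoints[, "y"], centroid[1], centroid[2])
  jidx <- which(joint_zones > 0)
  jrc <- arrayInd(jidx, dim(joint_zones))
  jq <- if (length(jidx)) quadrant_of(jrc[, 2], jrc[, 1], centroid[1], centroid[2])
        else character(0)
  out <- stats::setNames(vector("list", 4), limbs)
  valid <- stats::setNames(rep(FALSE, 4), limbs)
  for (limb in limbs) {
    cand <- which(epq == limb)
    if (length(cand) == 0) next
    jx <- jrc[jq == limb, 2]; jy <- jrc[jq == limb, 1]
    dist_of <- function(i) {
      if (length(jx) == 0)
        return(sqrt((endpoints[i, "x"] - centroid[1])^2 +
                    (endpoints[i, "y"] - centroid[2])^2))
      min(sqrt((jx - endpoints[i, "x"])^2 + (jy - endpoints[i, "y"])^2))
    }
    d <- vapply(cand, dist_of, 1)
    best <- cand[order(-d, cand)[1]]
    out[[limb]] <- c(x = unname(endpoints[best, "x"] - centroid[1]),
                     y = unname(endpoints[best, "y"] - centroid[2]))
    valid[limb] <- TRUE
  }
  structure(list(frame_index = frame_index, centroid = centroid,
                 orientation = orientation, endpoints = out,
                 valid_limbs = valid),
            class = "froglet_pose")
}

#' Hindfoot angle-pair of a pose
#'
#' @param pose a `froglet_pose` from [assign_limbs()].
#' @return list `alpha_right`, `alpha_left` (degrees in `[0, 180)`),
#'   `frame_index`, `valid`; invalid when either hindfoot was not detected.
#' @export
compute_angle_pair <- function(pose) {
  if (!all(pose$valid_limbs[c("hind_right", "hind_left")])) {
    return(list(alpha_right = NA_real_, alpha_left = NA_real_,
                frame_index = pose$frame_index, valid = FALSE))
  }
  hr <- pose$endpoints$hind_right
  hl <- pose$endpoints$hind_left
  wrap <- function(a) a %% 360 %% 180
  list(alpha_right = wrap(atan2(hr["y"], hr["x"]) * 180 / pi),
       alpha_left = wrap(atan2(hl["y"], -hl["x"]) * 180 / pi),
       frame_index = pose$frame_index, valid = TRUE)
}

#' Full pose recovery for one detection
#'
#' Chains orientation estimation, head-up normalization, limb extraction,
#' skeletonization, endpoint assignment and the angle-pair computation. The
#' angle vertex and quadrant centre is the centroid of the limb-free
#' (opened) body, which tracks the renderer's body centre rather than
#' drifting with limb posture.
#'
#' @param detection a valid `froglet_detection` (or a bare logical mask).
#' @inheritParams extract_limbs
#' @return list `pose` (a `froglet_pose`) and `angles` (angle-pair list); or
#'   an invalid pose if the detection is invalid or any stage fails.
#' @export
frame_pose <- function(detection, erosion_radius = NULL, dilation_radius = 2,
                       min_limb_area = 15) {
  mask <- if (inherits(detection, "froglet_detection")) {
    if (!isTRUE(detection$valid)) return(invalid_pose(detection$frame_index))
    detection$mask
  } else detection
  fi <- if (inherits(detection, "froglet_detection")) detection$frame_index else NA_integer_
  tryCatch({
    r <- if (is.null(erosion_radius)) default_erosion_radius(mask) else erosion_radius
    ang <- estimate_orientation(mask, r)
    om <- normalize_orientation(mask, ang, r)
    parts <- extract_limbs(om, r, dilation_radius, min_limb_area)
    centroid <- mask_centroid(parts$body)
    eps <- skeleton_endpoints(parts$limb_mask)
    pose <- assign_limbs(eps, parts$joint_mask, centroid,
                         frame_index = fi, orientation = ang)
    list(pose = pose, angles = compute_angle_pair(pose))
  }, error = function(e) invalid_pose(fi, conditionMessage(e)))
}

invalid_pose <- function(frame_index, msg = NA_character_) {
  list(pose = NULL,
       angles = list(alpha_right = NA_real_, alpha_left = NA_real_,
                     frame_index = frame_index, valid = FALSE),
       error = msg)
}

#' Pose table for a tracked video
#'
#' @param detections list from [track_video()].
#' @inheritParams frame_pose
#' @return data.frame with one row per processed frame: `frame_index`,
#'   `valid`, `orientation_deg`, `alpha_right`, `alpha_left` and the
#'   centroid-relative endpoint coordinates `<limb>_x`, `<limb>_y`,
#'   `<limb>_valid` for the four limbs.
#' @export
pose_video <- function(detections, erosion_radius = NULL, dilation_radius = 2,
                       min_limb_area = 15) {
  limbs <- c("fore_right", "fore_left", "hind_right", "hind_left")
  rows <- lapply(detections, function(det) {
    fp <- frame_pose(det, erosion_radius, dilation_radius, min_limb_area)
    row <- list(frame_index = fp$angles$frame_index,
                valid = isTRUE(fp$angles$valid),
                orientation_deg = if (is.null(fp$pose)) NA_real_ else fp$pose$orientation,
                alpha_right = unname(fp$angles$alpha_right),
                alpha_left = unname(fp$angles$alpha_left))
    for (limb in limbs) {
      ok <- !is.null(fp$pose) && isTRUE(fp$pose$valid_limbs[[limb]])
      row[[paste0(limb, "_x")]] <- if (ok) unname(fp$pose$endpoints[[limb]]["x"]) else NA_real_
      row[[paste0(limb, "_y")]] <- if (ok) unname(fp$pose$endpoints[[limb]]["y"]) else NA_real_
      row[[paste0(limb, "_valid")]] <- ok
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
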