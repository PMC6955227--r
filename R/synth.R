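#' Hindlimb motion model
#'
#' Parametrizes the per-class swimming behaviour of a froglet's hindfeet as
#' noisy sinusoidal angle traces. Angles use the package convention: the
#' hindfoot angle is measured at the body centre between the lateral
#' direction of that side and the centroid-to-foot vector, sweeping toward
#' the tail, so 0 deg = foot pointing straight sideways and 90 deg = foot
#' pointing straight back. Mirror-symmetric postures give equal right/left
#' angles.
#'
#' @param amplitude_right,amplitude_left stroke amplitudes, degrees.
#' @param mean_angle_right,mean_angle_left mean foot angles, degrees.
#' @param phase_offset left-vs-right phase, radians (0 in-phase, pi anti-phase).
#' @param stroke_frequency strokes per second, Hz.
#' @param angle_noise_sd per-frame white angular noise, degrees.
#' @param phase_jitter_sd SD of a per-stroke random phase offset, radians.
#'   Each full stroke period of the left trace draws a fresh offset, which
#'   decorrelates the two feet (the "independent" swimming pattern) without
#'   destroying the within-stroke sinusoidal shape.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(amplitude_right, amplitude_left,
                         mean_angle_right, mean_angle_left,
                         phase_offset = 0, stroke_frequency = 2.5,
                         angle_noise_sd = 0, phase_jitter_sd = 0) {
  stopifnot(amplitude_right >= 0, amplitude_left >= 0,
            stroke_frequency > 0, angle_noise_sd >= 0, phase_jitter_sd >= 0)
  for (side in list(c(mean_angle_right, amplitude_right),
                    c(mean_angle_left, amplitude_left))) {
    if (side[1] - side[2] < 0 || side[1] + side[2] > 180)
      stop("mean angle +/- amplitude must stay within [0, 180] degrees")
  }
  structure(list(amplitude_right = amplitude_right,
                 amplitude_left = amplitude_left,
                 mean_angle_right = mean_angle_right,
                 mean_angle_left = mean_angle_left,
                 phase_offset = phase_offset,
                 stroke_frequency = stroke_frequency,
                 angle_noise_sd = angle_noise_sd,
                 phase_jitter_sd = phase_jitter_sd),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf(paste0("<motion_model> ampR %.1f ampL %.1f meanR %.1f meanL %.1f",
                     " phase %.2f rad, f %.2f Hz, noise %.1f deg, jitter %.2f rad\n"),
              x$amplitude_right, x$amplitude_left, x$mean_angle_right,
              x$mean_angle_left, x$phase_offset, x$stroke_frequency,
              x$angle_noise_sd, x$phase_jitter_sd))
  invisible(x)
}

#' Admissible damage classes
#' @export
damage_classes <- function() c("uninjured", "hemisected", "transected")

# Class-level base motion constants. Amplitudes/means keep every foot within
# its own body quadrant (angle + 3 SD of noise below 90 deg); see the methods
# vignette for the geometric argument and the calibration of the ranges.
motion_base <- function(label) {
  switch(label,
    uninjured  = list(ar = 37, al = 37, mr = 45, ml = 45,
                      phase = 0, f = 2.5, noise = 2, jitter = 0),
    hemisected = list(ar = 18, al = 37, mr = 30, ml = 45,
                      phase = 0, f = 2.5, noise = 2, jitter = pi),
    transected = list(ar = 10, al = 10, mr = 50, ml = 50,
                      phase = pi, f = 2.2, noise = 4, jitter = 0.2),
    stop("unknown damage class: ", label))
}

#' Default per-class motion model
#'
#' Returns the stock motion model for one damage class, with a seeded
#' animal-to-animal perturbation of the constants (amplitudes x U(0.9, 1.1),
#' means +/- 3 deg, stroke frequency x U(0.85, 1.15), noise x U(0.8, 1.2)).
#' The three classes emulate: synchronized large-amplitude strokes
#' (uninjured); a paralyzed right foot resting lateral-anterior with roughly
#' half the left amplitude and per-stroke phase decorrelation (hemisected);
#' and small anti-phase pelvis-driven oscillations (transected).
#'
#' @param label one of [damage_classes()].
#' @param seed integer; identical `(label, seed)` gives an identical model.
#' @export
default_motion_model <- function(label, seed = 1) {
  label <- match.arg(label, damage_classes())
  b <- motion_base(label)
  withr::with_seed(seed, {
    ja <- stats::runif(2, 0.9, 1.1)
    jm <- stats::runif(2, -3, 3)
    jf <- stats::runif(1, 0.85, 1.15)
    jn <- stats::runif(1, 0.8, 1.2)
  })
  motion_model(amplitude_right = b$ar * ja[1], amplitude_left = b$al * ja[2],
               mean_angle_right = b$mr + jm[1], mean_angle_left = b$ml + jm[2],
               phase_offset = b$phase, stroke_frequency = b$f * jf,
               angle_noise_sd = b$noise * jn, phase_jitter_sd = b$jitter)
}

#' Rendering parameters
#'
#' Geometry and photometry of the synthetic froglet. The animal is a dark
#' filled ellipse (body) with four one-segment limbs: each limb is a thick
#' line from a fixed anchor on the body boundary to the ground-truth foot or
#' hand position. The background must be strictly brighter than the animal
#' in the blue channel, which is what the segmentation thresholds on.
#'
#' @param frame_width,frame_height frame size, pixels.
#' @param body_semi_major,body_semi_minor body ellipse semi-axes, pixels
#'   (major axis along the head-tail direction).
#' @param limb_length distance from the body centre to a hindfoot, pixels.
#' @param limb_width hindlimb thickness, pixels.
#' @param fore_limb_length,fore_limb_width forelimb geometry, pixels.
#' @param foreground,background length-3 RGB intensities in `[0, 1]`.
#' @param swim_speed forward drift, pixels per frame.
#' @param fps frames per second.
#' @export
render_params <- function(frame_width = 480, frame_height = 360,
                          body_semi_major = 40, body_semi_minor = 24,
                          limb_length = 58, limb_width = 5,
                          fore_limb_length = 40, fore_limb_width = 4,
                          foreground = c(0.17, 0.16, 0.157),
                          background = c(0.78, 0.82, 0.902),
                          swim_speed = 0.5, fps = 60) {
  if (background[3] <= foreground[3])
    stop("background blue intensity must be strictly greater than foreground")
  stopifnot(limb_length > body_semi_major, frame_width > 0, frame_height > 0,
            fps > 0, swim_speed >= 0)
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 body_semi_major = body_semi_major,
                 body_semi_minor = body_semi_minor,
                 limb_length = limb_length, limb_width = limb_width,
                 fore_limb_length = fore_limb_length,
                 fore_limb_width = fore_limb_width,
                 foreground = foreground, background = background,
                 swim_speed = swim_speed, fps = fps),
            class = "render_params")
}

# fraction of the semi-axes at which limbs anchor on the body boundary
ANCHOR_T <- 35 * pi / 180

# Unit vectors of the body frame at heading h (degrees, screen convention).
body_axes <- function(heading_deg) {
  th <- heading_deg * pi / 180
  anterior <- c(cos(th), sin(th))
  right <- c(-anterior[2], anterior[1])   # +90 deg on screen; head-up => image right
  list(anterior = anterior, right = right, posterior = -anterior)
}

# Foot/hand positions implied by the angles, full-frame coordinates.
limb_endpoints_for <- function(cx, cy, heading_deg, aR, aL, gR, gL, params) {
  ax <- body_axes(heading_deg)
  Rh <- params$limb_length; Rf <- params$fore_limb_length
  d2r <- pi / 180
  pt <- function(radius, lon, lat) {
    # lon along +-right, lat along posterior
    c(cx, cy) + radius * (lon * ax$right + lat * ax$posterior)
  }
  list(hind_right = pt(Rh, cos(aR * d2r), sin(aR * d2r)),
       hind_left  = pt(Rh, -cos(aL * d2r), sin(aL * d2r)),
       fore_right = pt(Rf, cos(gR * d2r), -sin(gR * d2r)),
       fore_left  = pt(Rf, -cos(gL * d2r), -sin(gL * d2r)))
}

limb_anchors_for <- function(cx, cy, heading_deg, params) {
  ax <- body_axes(heading_deg)
  bx <- params$body_semi_minor * sin(ANCHOR_T)
  by <- params$body_semi_major * cos(ANCHOR_T)
  pt <- function(lon, lat) c(cx, cy) + lon * ax$right + lat * ax$posterior
  list(hind_right = pt(bx, by), hind_left = pt(-bx, by),
       fore_right = pt(bx, -by), fore_left = pt(-bx, -by))
}

#' Generate ground-truth swimming traces
#'
#' Simulates the per-frame hindfoot angle-pair plus forelimb angles, body
#' path and heading, and the implied limb endpoint positions. Hind angles
#' follow `mean + amplitude * sin(2 pi f t (+ phase))` with optional white
#' angular noise and per-stroke phase jitter on the left trace; values are
#' clipped to `[0, 180)`. The body drifts forward at constant speed along a
#' seeded heading with a small sinusoidal heading wobble (the rendered
#' counterpart of pelvis motion).
#'
#' @param model a [motion_model()].
#' @param n_frames number of frames (>= 2).
#' @param fps frames per second.
#' @param seed integer seed; identical inputs give bit-identical traces.
#' @param params a [render_params()] supplying frame geometry for the path.
#' @return data.frame of class `froglet_traces`, one row per frame.
#' @export
generate_traces <- function(model, n_frames, fps = 60, seed = 1,
                            params = render_params(fps = fps)) {
  stopifnot(inherits(model, "motion_model"), n_frames >= 2)
  tt <- (seq_len(n_frames) - 1) / fps
  w <- 2 * pi * model$stroke_frequency
  withr::with_seed(seed, {
    heading_base <- stats::runif(1, 0, 360)
    wobble_phase <- stats::runif(1, 0, 2 * pi)
    n_strokes <- floor(model$stroke_frequency * max(tt)) + 1
    jit <- if (model$phase_jitter_sd > 0)
      stats::rnorm(n_strokes, 0, model$phase_jitter_sd) else numeric(n_strokes)
    noise_r <- stats::rnorm(n_frames, 0, model$angle_noise_sd)
    noise_l <- stats::rnorm(n_frames, 0, model$angle_noise_sd)
    noise_f <- stats::rnorm(2 * n_frames, 0, model$angle_noise_sd / 2)
  })
  stroke <- pmin(floor(model$stroke_frequency * tt) + 1, n_strokes)
  aR <- model$mean_angle_right + model$amplitude_right * sin(w * tt) + noise_r
  aL <- model$mean_angle_left +
    model$amplitude_left * sin(w * tt + model$phase_offset + jit[stroke]) + noise_l
  clip <- function(a) pmin(pmax(a, 0), 180 - 1e-9)
  aR <- clip(aR); aL <- clip(aL)
  # forelimbs: small in-phase paddling, tracked but unused by the features
  gR <- clip(45 + 8 * sin(w * tt) + noise_f[seq_len(n_frames)])
  gL <- clip(45 + 8 * sin(w * tt) + noise_f[n_frames + seq_len(n_frames)])

  heading <- heading_base + 4 * sin(w * tt + wobble_phase)
  dirv <- c(cos(heading_base * pi / 180), sin(heading_base * pi / 180))
  travel <- params$swim_speed * (seq_len(n_frames) - 1)
  centre <- c(params$frame_width, params$frame_height) / 2
  start <- centre - dirv * params$swim_speed * (n_frames - 1) / 2
  cx <- start[1] + dirv[1] * travel
  cy <- start[2] + dirv[2] * travel

  ep <- mapply(function(x, y, h, ar, al, gr, gl)
    unlist(limb_endpoints_for(x, y, h, ar, al, gr, gl, params)),
    cx, cy, heading, aR, aL, gR, gL)
  out <- data.frame(frame = seq_len(n_frames), time_s = tt,
                    cx = cx, cy = cy, heading_deg = heading,
                    alpha_right = aR, alpha_left = aL,
                    gamma_right = gR, gamma_left = gL,
                    hind_right_x = ep["hind_right1", ], hind_right_y = ep["hind_right2", ],
                    hind_left_x = ep["hind_left1", ], hind_left_y = ep["hind_left2", ],
                    fore_right_x = ep["fore_right1", ], fore_right_y = ep["fore_right2", ],
                    fore_left_x = ep["fore_left1", ], fore_left_y = ep["fore_left2", ])
  attr(out, "fps") <- fps
  attr(out, "model") <- model
  attr(out, "params") <- params
  class(out) <- c("froglet_traces", "data.frame")
  out
}

animal_extent <- function(params) params$limb_length + params$limb_width / 2 + 2

check_in_frame <- function(traces, params) {
  ext <- animal_extent(params)
  ok <- traces$cx - ext >= 1 & traces$cx + ext <= params$frame_width &
    traces$cy - ext >= 1 & traces$cy + ext <= params$frame_height
  if (!all(ok))
    stop("limb geometry exits the frame at frame(s) ",
         paste(utils::head(traces$frame[!ok], 3), collapse = ", "),
         "; reduce swim_speed, n_frames or the limb geometry")
  invisible(TRUE)
}

seg_dist2 <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / len2, 0), 1)
  dx <- px - (a[1] + t * vx); dy <- py - (a[2] + t * vy)
  dx * dx + dy * dy
}

#' Render one frame of a synthetic video
#'
#' @param trace_row single row of a `froglet_traces` data.frame.
#' @param params a [render_params()].
#' @return RGB array `frame_height x frame_width x 3`. Rendering is hard-edged
#'   (no anti-aliasing) so the animal's pixel area is exact and any blue
#'   threshold between the two intensities recovers the same mask.
#' @export
render_frame <- function(trace_row, params) {
  h <- params$frame_height; w <- params$frame_width
  frame <- array(rep(params$background, each = h * w), c(h, w, 3))
  ext <- ceiling(animal_extent(params))
  r0 <- max(1, floor(trace_row$cy) - ext); r1 <- min(h, ceiling(trace_row$cy) + ext)
  c0 <- max(1, floor(trace_row$cx) - ext); c1 <- min(w, ceiling(trace_row$cx) + ext)
  xs <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  ys <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)

  ax <- body_axes(trace_row$heading_deg)
  dx <- xs - trace_row$cx; dy <- ys - trace_row$cy
  u <- dx * ax$anterior[1] + dy * ax$anterior[2]
  v <- dx * ax$right[1] + dy * ax$right[2]
  inside <- (u / params$body_semi_major)^2 + (v / params$body_semi_minor)^2 <= 1

  anchors <- limb_anchors_for(trace_row$cx, trace_row$cy, trace_row$heading_deg, params)
  feet <- list(hind_right = c(trace_row$hind_right_x, trace_row$hind_right_y),
               hind_left = c(trace_row$hind_left_x, trace_row$hind_left_y),
               fore_right = c(trace_row$fore_right_x, trace_row$fore_right_y),
               fore_left = c(trace_row$fore_left_x, trace_row$fore_left_y))
  for (limb in names(feet)) {
    wdth <- if (grepl("^hind", limb)) params$limb_width else params$fore_limb_width
    inside <- inside | seg_dist2(xs, ys, anchors[[limb]], feet[[limb]]) <= (wdth / 2)^2
  }
  for (k in 1:3) {
    plane <- frame[, , k]
    sub <- plane[r0:r1, c0:c1]
    sub[inside] <- params$foreground[k]
    plane[r0:r1, c0:c1] <- sub
    frame[, , k] <- plane
  }
  frame
}

#' Lazy synthetic video
#'
#' Wraps ground-truth traces as a [frog_video] whose frames are rendered on
#' demand, avoiding any intermediate files.
#'
#' @inheritParams render_frame
#' @param traces a `froglet_traces` data.frame from [generate_traces()].
#' @export
synthetic_video <- function(traces, params = attr(traces, "params")) {
  check_in_frame(traces, params)
  new_frog_video(function(i) render_frame(traces[i, ], params),
                 nrow(traces), params$frame_width, params$frame_height,
                 attr(traces, "fps") %||% params$fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic video to disk
#'
#' Writes numbered PNG frames (`frame_000001.png`, ...) plus a sidecar
#' `ground_truth.csv` holding the full trace table (per-frame centroid,
#' heading, hindfoot angle-pair, forelimb angles and all four limb
#' endpoints).
#'
#' @inheritParams synthetic_video
#' @param out_dir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
render_video <- function(traces, params = attr(traces, "params"), out_dir) {
  check_in_frame(traces, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  for (i in seq_len(nrow(traces))) {
    write_frame_png(render_frame(traces[i, ], params),
                    file.path(out_dir, sprintf("frame_%06d.png", i)))
  }
  utils::write.csv(as.data.frame(traces),
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Read a ground-truth sidecar table
#' @param path directory written by [render_video()] or the CSV file itself.
#' @export
read_ground_truth <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "ground_truth.csv") else path
  utils::read.csv(f)
}
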