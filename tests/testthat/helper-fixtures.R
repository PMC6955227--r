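# Shared fixtures, all generated in code. Expensive synthetic videos are
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small tracked synthetic video of one class: traces, video, area range,
# detections (step 2) and pose table.
tracked_fixture <- function(label, n_frames = 60, model_seed = 3, trace_seed = 5) {
  fixture(paste("tracked", label, n_frames, model_seed, trace_seed, sep = "_"), function() {
    model <- default_motion_model(label, seed = model_seed)
    traces <- generate_traces(model, n_frames, fps = 60, seed = trace_seed)
    video <- synthetic_video(traces, render_params())
    rng <- calibrate_area(video, seed = 2)
    dets <- track_video(video, rng, frame_step = 2)
    poses <- pose_video(dets)
    list(model = model, traces = traces, video = video, range = rng,
         detections = dets, poses = poses)
  })
}

# Filled ellipse mask, axis angle in screen degrees (90 = vertical).
ellipse_mask <- function(h = 121, w = 121, cx = 61, cy = 61, a = 40, b = 20,
                         angle = 90) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ys <- matrix(seq_len(h), h, w) - cy
  th <- angle * pi / 180
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Frame with rectangles of given pixel areas (single channel intensity fg on
# bg), used by the calibration and area-filter tests.
blob_frame <- function(rects, h = 200, w = 300, fg = c(0.2, 0.2, 0.15),
                       bg = c(0.8, 0.8, 0.9)) {
  frame <- array(rep(bg, each = h * w), c(h, w, 3))
  for (r in rects) {
    rows <- r$y:(r$y + r$rows - 1)
    cols <- r$x:(r$x + r$cols - 1)
    for (k in 1:3) frame[rows, cols, k] <- fg[k]
  }
  frame
}

# Minimal hand-built pose object for angle-convention tests.
fake_pose <- function(hr, hl, frame_index = 1L) {
  structure(list(frame_index = frame_index, centroid = c(x = 0, y = 0),
                 orientation = 90,
                 endpoints = list(fore_right = c(x = 10, y = -10),
                                  fore_left = c(x = -10, y = -10),
                                  hind_right = c(x = hr[1], y = hr[2]),
                                  hind_left = c(x = hl[1], y = hl[2])),
                 valid_limbs = c(fore_right = TRUE, fore_left = TRUE,
                                 hind_right = TRUE, hind_left = TRUE)),
            class = "froglet_pose")
}

# Brute-force 180x180 binning oracle, independent of build_histogram.
brute_histogram <- function(alpha_right, alpha_left) {
  m <- matrix(0L, 180, 180)
  for (i in seq_along(alpha_right)) {
    r <- min(floor(alpha_right[i]), 179) + 1
    l <- min(floor(alpha_left[i]), 179) + 1
    m[r, l] <- m[r, l] + 1L
  }
  m
}

# Smallest circular difference between two angles modulo `period` degrees.
ang_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

expect_angles_close <- function(recovered, truth, tol, period = 360) {
  expect_lt(max(ang_diff(recovered, truth, period), na.rm = TRUE), tol)
}
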