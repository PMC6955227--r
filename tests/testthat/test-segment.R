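# Segmentation: blue threshold, area calibration, detection and tracking.

test_that("blue thresholding separates animal from background and flags degenerate input", {
  frame <- blob_frame(list(list(x = 50, y = 60, rows = 10, cols = 10)))
  mask <- threshold_blue(frame)
  expect_identical(sum(mask), 100L + 0L)
  expect_error(threshold_blue(frame[, , 1, drop = FALSE]), "three colour channels")
  expect_error(threshold_blue(frame, method = "fixed"), "fixed_value")

  uniform <- array(0.5, c(40, 40, 3))
  m <- threshold_blue(uniform)
  expect_true(attr(m, "degenerate"))
  expect_false(any(m))

  # inverted polarity: bright animal on dark background must be rejected
  # unless the polarity flag says so
  inv <- frame
  inv[, , 3] <- 1 - inv[, , 3]
  expect_error(threshold_blue(inv), "polarity")
  expect_identical(sum(threshold_blue(inv, polarity = "light")), 100L + 0L)
})

test_that("area range is the +/-10% band around the calibration area", {
  rng <- area_range(100)
  expect_equal(rng$lower_bound, 90)
  expect_equal(rng$upper_bound, 110)
  expect_error(area_range(0))
})

test_that("calibration takes the median over sampled frames, robust to one outlier", {
  # six frames holding single rectangles of area 98,100,100,100,102,300
  rects <- list(list(x = 20, y = 20, rows = 7, cols = 14),    # 98
                list(x = 40, y = 40, rows = 10, cols = 10),   # 100
                list(x = 60, y = 60, rows = 10, cols = 10),   # 100
                list(x = 80, y = 80, rows = 10, cols = 10),   # 100
                list(x = 100, y = 100, rows = 6, cols = 17),  # 102
                list(x = 120, y = 50, rows = 15, cols = 20))  # 300
  frames <- lapply(rects, function(r) blob_frame(list(r)))
  video <- video_from_frames(frames)
  rng <- calibrate_area(video, n_frames = 6, seed = 1)
  expect_equal(rng$calibration_area, 100)
  expect_equal(rng$lower_bound, 90)
  expect_equal(rng$upper_bound, 110)

  same <- video_from_frames(rep(frames[2], 6))
  rng2 <- calibrate_area(same, n_frames = 6, seed = 1)
  expect_equal(c(rng2$lower_bound, rng2$upper_bound), c(90, 110))

  blank <- video_from_frames(rep(list(array(0.5, c(50, 50, 3))), 6))
  expect_error(calibrate_area(blank, n_frames = 6, seed = 1), "no animal")
})

test_that("calibration on a synthetic video brackets the true rendered area", {
  fx <- tracked_fixture("uninjured")
  true_areas <- vapply(seq_len(60), function(i)
    sum(threshold_blue(get_frame(fx$video, i))), 1)
  inside <- true_areas >= fx$range$lower_bound & true_areas <= fx$range$upper_bound
  expect_gte(mean(inside), 0.99)
})

test_that("the area filter keeps exactly the in-range component", {
  # components at 0.5x, 1.0x and 3x the calibration area 100
  frame <- blob_frame(list(list(x = 30, y = 30, rows = 5, cols = 10),    # 50
                           list(x = 120, y = 100, rows = 10, cols = 10), # 100
                           list(x = 200, y = 30, rows = 15, cols = 20))) # 300
  det <- detect_froglet(frame, area_range(100))
  expect_true(det$valid)
  expect_equal(det$area, 100)
  expect_equal(det$centroid, c(124.5, 104.5), tolerance = 1e-9)

  # nothing in range -> invalid detection
  det2 <- detect_froglet(frame, area_range(1000))
  expect_false(det2$valid)
})

test_that("among in-range components the one nearest the previous detection wins", {
  frame <- blob_frame(list(list(x = 50, y = 50, rows = 10, cols = 10),
                           list(x = 200, y = 120, rows = 10, cols = 10)),
                      h = 250, w = 350)
  rng <- area_range(100)
  prev <- detect_froglet(blob_frame(list(list(x = 60, y = 60, rows = 10, cols = 10)),
                                    h = 250, w = 350), rng)
  det <- detect_froglet(frame, rng, prev = prev, window_side = 301)
  expect_lt(det$centroid[1], 100)   # picked the nearby blob, not the far one
})

test_that("tracking processes every n-th frame and follows the ground-truth path", {
  fx <- tracked_fixture("uninjured")
  expect_length(fx$detections, ceiling(60 / 2))
  expect_true(all(vapply(fx$detections, `[[`, TRUE, "valid")))
  tab <- detections_table(fx$detections)
  idx <- tab$frame_index
  # the tracked centroid is the whole-animal centroid, which sits ~2 px
  # posterior of the sidecar body centre because of hindlimb mass; the
  # trajectory itself must follow the body-centre path tightly
  err_x <- tab$cx - fx$traces$cx[idx]
  err_y <- tab$cy - fx$traces$cy[idx]
  rmse <- sqrt(mean(err_x^2 + err_y^2))
  expect_lt(rmse, 3)
  drift_rmse <- sqrt(mean((err_x - mean(err_x))^2 + (err_y - mean(err_y))^2))
  expect_lt(drift_rmse, 2)

  dets1 <- track_video(fx$video, fx$range, frame_step = 1)
  expect_length(dets1, 60)
  expect_length(track_video(fx$video, fx$range, frame_step = 7), ceiling(60 / 7))
})

test_that("tracking is translation-equivariant", {
  fx <- tracked_fixture("uninjured")
  shifted <- video_map(fx$video, function(f) translate_frame(f, 5, 7))
  dets <- track_video(shifted, fx$range, frame_step = 2)
  tab0 <- detections_table(fx$detections)
  tab1 <- detections_table(dets)
  expect_equal(tab1$cx, tab0$cx + 5, tolerance = 1e-9)
  expect_equal(tab1$cy, tab0$cy + 7, tolerance = 1e-9)
})

test_that("tracking marks occluded frames invalid and re-acquires afterwards", {
  fx <- tracked_fixture("uninjured")
  params <- render_params()
  bg <- array(rep(params$background, each = params$frame_height * params$frame_width),
              c(params$frame_height, params$frame_width, 3))
  occluded <- froglet:::new_frog_video(function(i) {
    if (i >= 21 && i <= 27) bg else fx$video$get_frame(i)
  }, 60, params$frame_width, params$frame_height, 60)
  dets <- track_video(occluded, fx$range, frame_step = 2)
  tab <- detections_table(dets)
  gone <- tab$frame_index >= 21 & tab$frame_index <= 27
  expect_true(all(!tab$valid[gone]))
  expect_true(all(tab$valid[!gone]))
  after <- which(tab$frame_index > 27)
  expect_lt(abs(tab$cx[after[1]] - fx$traces$cx[tab$frame_index[after[1]]]), 2)
})
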