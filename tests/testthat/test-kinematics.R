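# Kinematics: joint-angle histogram, heatmap normalization, the four features.

test_that("histogram bins angle-pairs at 1-degree resolution", {
  pairs <- data.frame(alpha_right = c(49.2, 52.9), alpha_left = c(88.7, 45.0))
  h <- build_histogram(pairs)
  expect_identical(dim(h), c(180L, 180L))
  expect_identical(h[49 + 1, 88 + 1], 1L)
  expect_identical(h[52 + 1, 45 + 1], 1L)
  expect_identical(sum(h), 2L)

  expect_identical(sum(build_histogram(data.frame(alpha_right = numeric(0),
                                                  alpha_left = numeric(0)))), 0L)

  rep1k <- data.frame(alpha_right = rep(10.5, 1000), alpha_left = rep(170.5, 1000))
  h <- build_histogram(rep1k)
  expect_identical(h[11, 171], 1000L)
  expect_identical(sum(h), 1000L)

  # clamping at the 180-degree edge and skipping invalid pairs
  edge <- data.frame(alpha_right = c(180, 20), alpha_left = c(0, NA),
                     valid = c(TRUE, TRUE))
  h <- build_histogram(edge)
  expect_identical(h[180, 1], 1L)
  expect_identical(sum(h), 1L)
})

test_that("histogram conserves counts, matching a brute-force binning oracle", {
  withr::with_seed(42, {
    for (rep in 1:3) {
      n <- sample(50:300, 1)
      ar <- stats::runif(n, 0, 180)
      al <- stats::runif(n, 0, 180)
      h <- build_histogram(data.frame(alpha_right = ar, alpha_left = al))
      expect_identical(sum(h), as.integer(n))
      expect_identical(unclass(h), brute_histogram(ar, al))
    }
  })
})

test_that("heatmap normalization is min-max with an all-equal degenerate rule", {
  h <- matrix(0L, 180, 180); h[7, 9] <- 10L
  n <- normalize_heatmap(h)
  expect_equal(n[7, 9], 1)
  expect_equal(sum(n), 1)

  expect_true(all(normalize_heatmap(matrix(0L, 180, 180)) == 0))
  expect_true(all(normalize_heatmap(matrix(5L, 180, 180)) == 0))

  withr::with_seed(1, {
    h <- matrix(rpois(180 * 180, 3), 180, 180)
    n <- normalize_heatmap(h)
    expect_equal(range(n), c(0, 1))
    oracle <- (h - min(h)) / (max(h) - min(h))   # elementwise brute force
    expect_equal(n, oracle)
  })
})

test_that("synchronization is the correlation of the two traces with analytic anchors", {
  t <- seq(0, 2, by = 1 / 60)
  s <- 90 + 40 * sin(2 * pi * 2.5 * t)
  expect_equal(synchronization(data.frame(alpha_right = s, alpha_left = s)), 1)
  expect_equal(synchronization(data.frame(alpha_right = 180 - s, alpha_left = s)), -1)
  # invariance under adding a constant and under swapping the feet
  o <- 90 + 40 * sin(2 * pi * 2.5 * t + 1)
  p <- data.frame(alpha_right = s, alpha_left = o)
  expect_equal(synchronization(p),
               synchronization(data.frame(alpha_right = o, alpha_left = s)))
  expect_equal(synchronization(p),
               synchronization(data.frame(alpha_right = s + 7, alpha_left = o)))
  expect_gte(synchronization(p), -1)
  expect_lte(synchronization(p), 1)

  expect_error(synchronization(data.frame(alpha_right = 1, alpha_left = 2)),
               "fewer than 2")
  expect_error(synchronization(data.frame(alpha_right = c(5, 5), alpha_left = c(1, 2))),
               "zero variance")
})

test_that("symmetry is the through-origin regression slope", {
  t <- seq(0, 2, by = 1 / 60)
  s <- 90 + 35 * sin(2 * pi * 2.5 * t)
  expect_equal(symmetry(data.frame(alpha_right = s, alpha_left = s)), 1)
  expect_equal(symmetry(data.frame(alpha_right = 0.5 * s, alpha_left = s)), 0.5)
  # through-origin slope scales exactly linearly in the right trace
  o <- 70 + 20 * sin(2 * pi * 2.5 * t + 0.7)
  b <- symmetry(data.frame(alpha_right = o, alpha_left = s))
  expect_equal(symmetry(data.frame(alpha_right = 3.25 * o, alpha_left = s)), 3.25 * b)
  # matches lm through the origin
  expect_equal(b, unname(coef(lm(o ~ s - 1))))
  # intercept variant matches ordinary lm
  expect_equal(symmetry(data.frame(alpha_right = o, alpha_left = s), intercept = TRUE),
               unname(coef(lm(o ~ s))[2]))
  expect_error(symmetry(data.frame(alpha_right = c(1, 2), alpha_left = c(0, 0))),
               "identically zero")
})

test_that("foot range matches a raw-extremes oracle on noiseless arcs", {
  for (half_angle in c(20, 35, 50)) {
    ang <- seq(50 - half_angle, 50 + half_angle, length.out = 400)
    pos <- angles_to_positions(ang, "right", radius = 58)
    oracle <- max(ang) - min(ang)   # raw min/max angle over the points
    est <- foot_range(pos, kde_bandwidth = 2, density_threshold_fraction = 0.2)
    expect_lt(abs(est - oracle), 5)
    # same arc on the left side must give the same range (no branch-cut blowup)
    posL <- angles_to_positions(ang, "left", radius = 58)
    estL <- foot_range(posL, kde_bandwidth = 2, density_threshold_fraction = 0.2)
    expect_equal(estL, est, tolerance = 1.5)
  }
})

test_that("foot range degenerates gracefully and is rotation invariant", {
  still <- data.frame(x = rep(40, 50), y = rep(40, 50))
  expect_lt(foot_range(still), 10)   # at most one smoothing kernel footprint
  expect_error(foot_range(data.frame(x = numeric(0), y = numeric(0))),
               "at least one")
  expect_error(foot_range(data.frame(x = c(1, 30), y = c(40, 40)),
                          density_threshold_fraction = 2), "threshold too high")

  # rotating positions rigidly with the convention axes leaves the arc width
  withr::with_seed(3, ang <- runif(300, 20, 80))
  pos <- as.matrix(angles_to_positions(ang, "right", 58))
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- pos %*% t(R)
  colnames(rot) <- c("x", "y")
  expect_equal(foot_range(rot), foot_range(pos), tolerance = 1.5)
})

test_that("extract_features assembles the four features with missing flags", {
  m <- motion_model(30, 30, 70, 70, phase_offset = 0, angle_noise_sd = 0)
  tr <- generate_traces(m, 240, fps = 60, seed = 1)
  fe <- extract_features(tr)
  expect_equal(fe$f1_synchronization, 1, tolerance = 1e-9)
  expect_equal(fe$f2_symmetry, 1, tolerance = 1e-9)
  expect_equal(fe$n_valid_frames, 240)
  expect_false(any(fe$missing))

  # a motionless limb: synchronization undefined -> flagged missing, not zeroed
  flat <- generate_traces(motion_model(0, 30, 60, 70, angle_noise_sd = 0),
                          120, fps = 60, seed = 1)
  fe2 <- extract_features(flat)
  expect_true(is.na(fe2$f1_synchronization))
  expect_true(fe2$missing[["f1"]])
  expect_false(fe2$missing[["f2"]])
})

test_that("synthetic class fingerprints land in their expected feature regions", {
  he <- generate_traces(default_motion_model("hemisected", seed = 2), 600,
                        fps = 60, seed = 3)
  fe <- extract_features(he)
  expect_lt(abs(fe$f1_synchronization), 0.3)       # independent movement
  expect_equal(fe$f2_symmetry, 0.5, tolerance = 0.1)

  un <- extract_features(generate_traces(default_motion_model("uninjured", 2),
                                         600, fps = 60, seed = 3))
  tr <- extract_features(generate_traces(default_motion_model("transected", 2),
                                         600, fps = 60, seed = 3))
  expect_gt(un$f1_synchronization, 0.9)
  expect_lt(tr$f1_synchronization, -0.4)
  expect_lt(tr$f3_range_right, un$f3_range_right)  # monotone in amplitude
  expect_lt(tr$f4_range_left, un$f4_range_left)
})

test_that("the heatmap PNG renderer writes a valid image with overlays", {
  pairs <- data.frame(alpha_right = runif(200, 30, 90),
                      alpha_left = runif(200, 30, 90))
  h <- build_histogram(pairs)
  path <- withr::local_tempfile(fileext = ".png")
  write_heatmap_png(h, path, slope = 0.8)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], c(360L, 360L))
})
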