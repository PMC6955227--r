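# Pose: orientation, head-up normalization, limb extraction, skeleton
# endpoints, quadrant assignment and the angle-pair convention.

test_that("orientation of synthetic bodies is recovered and degenerate shapes rejected", {
  expect_equal(estimate_orientation(ellipse_mask(angle = 90), erosion_radius = 3), 90,
               tolerance = 0.5)
  expect_equal(estimate_orientation(ellipse_mask(angle = 0), erosion_radius = 3), 0,
               tolerance = 0.5)
  expect_equal(estimate_orientation(ellipse_mask(angle = 40), erosion_radius = 3), 40,
               tolerance = 1)
  circle <- ellipse_mask(a = 30, b = 30)
  expect_error(estimate_orientation(circle, erosion_radius = 3), "degenerate")
  expect_error(estimate_orientation(ellipse_mask(), erosion_radius = 60), "empty")
})

test_that("rendered heading is recovered within 2 degrees (mod 180)", {
  fx <- tracked_fixture("uninjured")
  for (k in c(1, 8, 15)) {
    det <- fx$detections[[k]]
    ang <- estimate_orientation(det$mask)
    truth <- fx$traces$heading_deg[det$frame_index]
    expect_angles_close(ang, truth, tol = 2, period = 180)
  }
})

test_that("head-up normalization flips by the pixel-count rule and is involutive", {
  fx <- tracked_fixture("uninjured")
  det <- fx$detections[[3]]
  ang <- estimate_orientation(det$mask)
  up <- normalize_orientation(det$mask, ang)
  # hindfeet (heavier half) must end up at the bottom: in the oriented frame
  # the hind endpoints are farther from the centre than the fore ones
  parts <- extract_limbs(up)
  cen <- mask_centroid(parts$body)
  eps <- skeleton_endpoints(parts$limb_mask)
  below <- eps[eps[, "y"] > cen["y"] + 5, , drop = FALSE]
  above <- eps[eps[, "y"] < cen["y"] - 5, , drop = FALSE]
  dist_max <- function(m) max(sqrt((m[, "x"] - cen["x"])^2 + (m[, "y"] - cen["y"])^2))
  expect_gt(dist_max(below), dist_max(above))  # hind feet are longer than hands

  # flipping the input 180 deg must give the same upright output
  flipped <- det$mask[nrow(det$mask):1, ncol(det$mask):1]
  ang2 <- estimate_orientation(flipped)
  up2 <- normalize_orientation(flipped, ang2)
  expect_angles_close(attr(up2, "rotation"), attr(up, "rotation") + 180, tol = 1)
  inter <- sum(up & up2) / sum(up | up2)
  expect_gt(inter, 0.97)                       # same mask up to interpolation

  # a top/bottom symmetric mask must not flip (strict inequality rule)
  sym <- ellipse_mask(angle = 90)
  upright <- normalize_orientation(sym, 90)
  expect_equal(attr(upright, "rotation"), 0)
})

test_that("limb extraction yields four limb components with joints, and fails on limbless bodies", {
  fx <- tracked_fixture("uninjured")
  det <- fx$detections[[5]]
  up <- normalize_orientation(det$mask, estimate_orientation(det$mask))
  parts <- extract_limbs(up)
  expect_equal(parts$n_limbs, 4)
  expect_gte(max(parts$joint_mask), 4)
  expect_error(extract_limbs(ellipse_mask()), "no limb components")
  expect_error(extract_limbs(matrix(FALSE, 10, 10)), "empty mask")
})

test_that("skeleton endpoints are the free ends of thin structures", {
  line <- matrix(0, 30, 30)
  line[15, 6:25] <- 1
  eps <- skeleton_endpoints(line)
  expect_identical(nrow(eps), 2L)
  expect_setequal(eps[, "x"], c(6, 25))

  ell <- matrix(0, 40, 40)
  ell[30, 5:30] <- 1
  ell[10:30, 30] <- 1   # L shape: the corner is not an endpoint
  eps <- skeleton_endpoints(ell)
  expect_identical(nrow(eps), 2L)
  expect_true(any(eps[, "x"] == 5 & eps[, "y"] == 30))
  expect_true(any(eps[, "x"] == 30 & eps[, "y"] == 10))

  expect_error(skeleton_endpoints(matrix(0, 5, 5)), "empty")
})

test_that("quadrant assignment keeps the endpoint farthest from its joint", {
  eps <- rbind(c(x = 30, y = 30), c(x = 12, y = 18),   # two in hind-right
               c(x = -25, y = 28), c(x = 28, y = -30), c(x = -27, y = -29))
  joints <- matrix(0L, 81, 81)
  joints[41 + 8, 41 + 8] <- 1L    # hind-right joint at (+8, +8) rel. centre
  joints[41 + 8, 41 - 8] <- 2L
  joints[41 - 8, 41 + 8] <- 3L
  joints[41 - 8, 41 - 8] <- 4L
  eps_abs <- eps
  eps_abs[, "x"] <- eps[, "x"] + 41
  eps_abs[, "y"] <- eps[, "y"] + 41
  pose <- assign_limbs(eps_abs, joints, centroid = c(41, 41))
  expect_true(all(pose$valid_limbs))
  expect_equal(unname(pose$endpoints$hind_right), c(30, 30))  # farther of the two
  expect_equal(unname(pose$endpoints$hind_left), c(-25, 28))
  expect_equal(unname(pose$endpoints$fore_right), c(28, -30))
  expect_error(assign_limbs(eps_abs[0, , drop = FALSE], joints, c(41, 41)),
               "at least one endpoint")

  # empty quadrant -> invalid limb
  pose2 <- assign_limbs(eps_abs[3:5, , drop = FALSE], joints, c(41, 41))
  expect_false(pose2$valid_limbs[["hind_right"]])
})

test_that("the angle-pair convention anchors at lateral 0 and posterior 90 and mirrors exactly", {
  lateral <- fake_pose(hr = c(30, 1e-9), hl = c(-30, 1e-9))
  ap <- compute_angle_pair(lateral)
  expect_equal(unname(ap$alpha_right), 0, tolerance = 1e-6)
  expect_equal(unname(ap$alpha_left), 0, tolerance = 1e-6)

  posterior <- fake_pose(hr = c(0, 30), hl = c(0, 30))
  ap <- compute_angle_pair(posterior)
  expect_equal(unname(ap$alpha_right), 90)
  expect_equal(unname(ap$alpha_left), 90)

  asym <- fake_pose(hr = c(20, 25), hl = c(-10, 40))
  mirrored <- fake_pose(hr = c(10, 40), hl = c(-20, 25))
  a1 <- compute_angle_pair(asym)
  a2 <- compute_angle_pair(mirrored)
  expect_equal(unname(a1$alpha_right), unname(a2$alpha_left), tolerance = 1e-12)
  expect_equal(unname(a1$alpha_left), unname(a2$alpha_right), tolerance = 1e-12)

  bad <- fake_pose(hr = c(20, 25), hl = c(-10, 40))
  bad$valid_limbs[["hind_left"]] <- FALSE
  expect_false(compute_angle_pair(bad)$valid)
})

test_that("recovered hind endpoints and angle-pairs match the renderer ground truth", {
  for (label in damage_classes()) {
    fx <- tracked_fixture(label)
    idx <- fx$poses$frame_index
    expect_gte(mean(fx$poses$valid), 0.95)
    maeR <- mean(abs(fx$poses$alpha_right - fx$traces$alpha_right[idx]), na.rm = TRUE)
    maeL <- mean(abs(fx$poses$alpha_left - fx$traces$alpha_left[idx]), na.rm = TRUE)
    expect_lt(maeR, 3)
    expect_lt(maeL, 3)
    biasR <- mean(fx$poses$alpha_right - fx$traces$alpha_right[idx], na.rm = TRUE)
    biasL <- mean(fx$poses$alpha_left - fx$traces$alpha_left[idx], na.rm = TRUE)
    expect_lt(abs(biasR), 1)
    expect_lt(abs(biasL), 1)
    # recovered hindfoot offsets sit at the rendered limb radius
    r <- sqrt(fx$poses$hind_right_x^2 + fx$poses$hind_right_y^2)
    expect_lt(abs(stats::median(r, na.rm = TRUE) - render_params()$limb_length), 4)
  }
})
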