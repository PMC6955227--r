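# Internal binary-image utilities shared by the segmentation and pose stages.
#
# Conventions used throughout the package:
#   * a mask is a numeric (0/1) or logical matrix indexed [row, col], row 1 on top;
#   * a point is c(x, y) with x = column and y = row, so y grows DOWNWARD;
#   * angles follow atan2(dy, dx) in these screen coordinates: 0 deg points
#     right, +90 deg points down; rotating a mask by +r deg adds r to the
#     angle of every direction.

as_mask <- function(x) {
  m <- (x > 0.5) * 1
  storage.mode(m) <- "double"
  m
}

disc_brush <- function(radius) {
  size <- 2L * as.integer(floor(radius)) + 1L
  if (size < 3L) return(matrix(1, 1, 1))
  EBImage::makeBrush(size, shape = "disc")
}

mask_erode <- function(mask, radius) {
  if (radius < 1) return(as_mask(mask))
  as_mask(EBImage::erode(as_mask(mask), disc_brush(radius)))
}

mask_dilate <- function(mask, radius) {
  if (radius < 1) return(as_mask(mask))
  as_mask(EBImage::dilate(as_mask(mask), disc_brush(radius)))
}

# Morphological opening: removes protrusions thinner than ~2*radius while
# reconstructing the large body region.
mask_open <- function(mask, radius) mask_dilate(mask_erode(mask, radius), radius)

label_components <- function(mask) EBImage::bwlabel(as_mask(mask))

# Per-component area and centroid (x = col, y = row).
component_stats <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(data.frame(label = integer(0), area = numeric(0),
                      cx = numeric(0), cy = numeric(0)))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  area <- tabulate(lab, nbins = n)
  sx <- rowsum(as.numeric(rc[, 2]), lab)
  sy <- rowsum(as.numeric(rc[, 1]), lab)
  data.frame(label = seq_len(n), area = area,
             cx = as.numeric(sx) / area, cy = as.numeric(sy) / area)
}

mask_centroid <- function(mask) {
  idx <- which(mask > 0.5)
  if (length(idx) == 0) stop("empty mask has no centroid")
  rc <- arrayInd(idx, dim(mask))
  c(x = mean(rc[, 2]), y = mean(rc[, 1]))
}

# Principal-axis angle of the foreground, degrees in (-90, 90] in screen
# coordinates (90 = vertical axis). Returns the major/minor eigenvalue ratio
# as an attribute so callers can detect degenerate (near-circular) regions.
principal_axis <- function(mask) {
  idx <- which(mask > 0.5)
  if (length(idx) < 3) stop("mask too small for an orientation estimate")
  rc <- arrayInd(idx, dim(mask))
  x <- rc[, 2] - mean(rc[, 2])
  y <- rc[, 1] - mean(rc[, 1])
  cxx <- mean(x * x); cyy <- mean(y * y); cxy <- mean(x * y)
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  tr <- cxx + cyy
  det <- cxx * cyy - cxy * cxy
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  structure(ang, axis_ratio = if (l2 > 0) l1 / l2 else Inf)
}

# Rotate a mask by `angle` degrees (positive = +x toward +y, i.e. clockwise on
# screen) about its canvas centre, expanding the canvas so nothing is lost.
# Bilinear interpolation followed by a 0.5 threshold keeps edges smooth.
rotate_mask <- function(mask, angle, expand = TRUE) {
  rotate_plane(as_mask(mask), angle, expand = expand, fill = 0) > 0.5
}

rotate_plane <- function(img, angle, expand = TRUE, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  if (expand) {
    side <- ceiling(sqrt(h^2 + w^2))
    if (side %% 2 == 0) side <- side + 1
    oh <- side; ow <- side
  } else {
    oh <- h; ow <- w
  }
  cin <- c((w + 1) / 2, (h + 1) / 2)
  cout <- c((ow + 1) / 2, (oh + 1) / 2)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  xs <- matrix(seq_len(ow), oh, ow, byrow = TRUE) - cout[1]
  ys <- matrix(seq_len(oh), oh, ow) - cout[2]
  # inverse map: source = R(-angle) %*% dest
  sx <- ct * xs + st * ys + cin[1]
  sy <- -st * xs + ct * ys + cin[2]
  bilinear_sample(img, sx, sy, fill)
}

bilinear_sample <- function(img, sx, sy, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get <- function(xx, yy) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- matrix(fill, nrow(sx), ncol(sx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- get(x0, y0); v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

shift_pad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning to a 1-pixel morphological skeleton. Operates on the
# bounding box of the foreground for speed; deterministic.
thin_mask <- function(mask) {
  m <- as_mask(mask)
  idx <- which(m > 0)
  if (length(idx) == 0) return(m)
  rc <- arrayInd(idx, dim(m))
  r0 <- max(1, min(rc[, 1]) - 1); r1 <- min(nrow(m), max(rc[, 1]) + 1)
  c0 <- max(1, min(rc[, 2]) - 1); c1 <- min(ncol(m), max(rc[, 2]) + 1)
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  sub <- zhang_suen(sub)
  out <- matrix(0, nrow(m), ncol(m))
  out[r0:r1, c0:c1] <- sub
  out
}

zhang_suen <- function(m) {
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise starting due north
      p2 <- shift_pad(m, 1, 0);  p3 <- shift_pad(m, 1, -1)
      p4 <- shift_pad(m, 0, -1); p5 <- shift_pad(m, -1, -1)
      p6 <- shift_pad(m, -1, 0); p7 <- shift_pad(m, -1, 1)
      p8 <- shift_pad(m, 0, 1);  p9 <- shift_pad(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-neighbour count of each foreground pixel.
neighbor_count <- function(m) {
  m <- as_mask(m)
  shift_pad(m, 1, 0) + shift_pad(m, -1, 0) + shift_pad(m, 0, 1) +
    shift_pad(m, 0, -1) + shift_pad(m, 1, 1) + shift_pad(m, 1, -1) +
    shift_pad(m, -1, 1) + shift_pad(m, -1, -1)
}

gaussian_kernel2d <- function(sigma) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

convolve2d <- function(img, kernel) {
  # EBImage::filter2 operates in the Fourier domain with circular padding;
  # pad with zeros first so density mass does not wrap around.
  kr <- nrow(kernel) %/% 2
  h <- nrow(img); w <- ncol(img)
  padded <- matrix(0, h + 2 * kr, w + 2 * kr)
  padded[(kr + 1):(kr + h), (kr + 1):(kr + w)] <- img
  out <- EBImage::filter2(padded, kernel, boundary = 0)
  out[(kr + 1):(kr + h), (kr + 1):(kr + w)]
}
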