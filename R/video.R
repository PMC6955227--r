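#' Video containers
#'
#' A `frog_video` is a lightweight handle on an ordered sequence of RGB
#' frames. Frames are fetched lazily through `get_frame(i)`, so a video can
#' be backed by an in-memory list, a directory of numbered PNG files, or a
#' renderer that draws frames on demand (see [synthetic_video()]). Each frame
#' is a `height x width x 3` array of intensities in `[0, 1]`.
#'
#' @param frames list of RGB arrays (all the same dimensions).
#' @param fps frames per second (metadata only).
#' @name frog_video
NULL

new_frog_video <- function(get_frame, n_frames, width, height, fps = 60) {
  structure(
    list(get_frame = get_frame, n_frames = as.integer(n_frames),
         width = as.integer(width), height = as.integer(height), fps = fps),
    class = "frog_video")
}

#' @rdname frog_video
#' @export
video_from_frames <- function(frames, fps = 60) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  stopifnot(length(d) == 3, d[3] == 3)
  new_frog_video(function(i) frames[[i]], length(frames), d[2], d[1], fps)
}

#' @rdname frog_video
#' @param path directory containing frames named `frame_000001.png`, ... in
#'   playback order (any zero-padded numbering sorts correctly).
#' @export
video_from_dir <- function(path, fps = 60) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", path)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 2) stop("frames must be RGB, not grayscale")
  new_frog_video(function(i) {
    f <- png::readPNG(files[i])
    f[, , 1:3, drop = FALSE]
  }, length(files), dim(first)[2], dim(first)[1], fps)
}

#' @export
print.frog_video <- function(x, ...) {
  cat(sprintf("<frog_video> %d frames, %dx%d px, %g fps\n",
              x$n_frames, x$width, x$height, x$fps))
  invisible(x)
}

n_frames <- function(video) video$n_frames

get_frame <- function(video, i) {
  if (i < 1 || i > video$n_frames) stop("frame index out of range: ", i)
  video$get_frame(i)
}

# Apply a per-frame transform lazily (used by the equivariance checks).
video_map <- function(video, f) {
  probe <- f(get_frame(video, 1))
  new_frog_video(function(i) f(video$get_frame(i)), video$n_frames,
                 dim(probe)[2], dim(probe)[1], video$fps)
}

#' Geometric frame transforms
#'
#' Helpers to rotate, mirror or translate whole RGB frames. These exist so
#' the pipeline's geometric contracts (rotation invariance of the recovered
#' angle-pairs, mirror equivariance of the right/left traces, translation
#' equivariance of tracking) can be exercised on real pixel data.
#'
#' @param frame RGB array `H x W x 3`.
#' @param angle degrees, positive rotates image content clockwise on screen.
#' @param fill length-3 RGB fill colour for exposed regions.
#' @return RGB array.
#' @export
rotate_frame <- function(frame, angle, fill = frame[1, 1, ]) {
  planes <- lapply(1:3, function(k)
    rotate_plane(frame[, , k], angle, expand = TRUE, fill = fill[k]))
  out <- array(0, c(nrow(planes[[1]]), ncol(planes[[1]]), 3))
  for (k in 1:3) out[, , k] <- planes[[k]]
  out
}

#' @rdname rotate_frame
#' @export
mirror_frame <- function(frame) frame[, ncol(frame[, , 1]):1, , drop = FALSE]

#' @rdname rotate_frame
#' @param dx,dy integer pixel shifts (positive = right/down).
#' @export
translate_frame <- function(frame, dx, dy, fill = frame[1, 1, ]) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  out <- array(rep(fill, each = h * w), c(h, w, 3))
  rs <- max(1, 1 + dy):min(h, h + dy)
  cs <- max(1, 1 + dx):min(w, w + dx)
  out[rs, cs, ] <- frame[rs - dy, cs - dx, , drop = FALSE]
  out
}

write_frame_png <- function(frame, path) {
  png::writePNG(frame, target = path)
}
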