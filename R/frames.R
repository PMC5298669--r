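#' Frame stacks
#'
#' A frame stack is an ordered list of grayscale frames plus a frame rate.
#' Each frame is a plain numeric matrix with intensities in \[0, 255\];
#' `frame[y + 1, x + 1]` is the pixel at 0-based image coordinates `(x, y)`,
#' with x increasing rightward and y increasing downward.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param fps Frames per second (must be positive).
#'
#' @return An object of class `frame_stack`: a list with elements `frames`
#'   and `fps`.
#' @export
#' @examples
#' fs <- frame_stack(list(matrix(128, 8, 8)), fps = 20)
#' length(fs$frames)
frame_stack <- function(frames, fps = 20) {
  stopifnot(is.list(frames), length(frames) >= 1, fps > 0)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimensions")
  structure(list(frames = frames, fps = fps), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack: %d frames, %d x %d px, %g fps>\n",
              length(x$frames), d[2], d[1], x$fps))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Time between consecutive frames
#'
#' @param fps Frame rate in frames per second.
#' @return The frame interval in seconds, `1 / fps`.
#' @export
#' @examples
#' round(frame_interval(19), 4)  # 0.0526
frame_interval <- function(fps) {
  stopifnot(is.numeric(fps), length(fps) == 1, fps > 0)
  1 / fps
}

#' Write a frame stack as numbered 8-bit grayscale PNGs
#'
#' Frames are rounded to integers, clipped to \[0, 255\] and written as
#' `frame_000001.png`, `frame_000002.png`, ... in `dir`.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(stack$frames)))
  for (i in seq_along(stack$frames)) {
    f <- pmin(pmax(round(stack$frames[[i]]), 0), 255)
    png::writePNG(f / 255, target = paths[i])
  }
  invisible(paths)
}

#' Read numbered grayscale PNG frames into a frame stack
#'
#' Reads every `*.png` in `dir` in lexicographic order. Color images are
#' converted to gray by channel averaging.
#'
#' @param dir Directory containing the frames.
#' @param fps Frame rate to attach (PNG carries none).
#' @return A [frame_stack()].
#' @export
read_frames <- function(dir, fps = 20) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0) stop("no .png frames found in ", dir)
  frames <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                          drop = FALSE], c(1, 2), mean)
    a * 255
  })
  frame_stack(frames, fps = fps)
}

# clip intensities into [0, 255]
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Euclidean distance matrix between two sets of points given as
# n x 2 matrices (columns x, y).
dist_xy <- function(p, q) {
  dx <- outer(p[, 1], q[, 1], "-")
  dy <- outer(p[, 2], q[, 2], "-")
  sqrt(dx^2 + dy^2)
}

# smallest absolute angle between two angles (radians), in [0, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
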