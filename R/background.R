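#' Extract a static background plate by per-pixel mode
#'
#' Because the flies move while the arena does not, the most frequent
#' intensity at a pixel across sampled frames is the background. `n_samples`
#' frames (default 100) are drawn without replacement; at each pixel the mode
#' of the sampled (8-bit quantized) values is taken. The estimate is exact
#' wherever the foreground occupies the pixel in fewer than half of the
#' sampled frames.
#'
#' @param frames A [frame_stack()] or list of frames.
#' @param n_samples Number of frames to sample (all frames if fewer exist).
#' @param seed Integer seed for the frame sampling.
#' @return An object of class `background_plate`: list with `image` (matrix),
#'   `mean_intensity`, and `n_samples`.
#' @export
#' @examples
#' fs <- frame_stack(list(matrix(7, 4, 4), matrix(7, 4, 4), matrix(9, 4, 4)))
#' extract_background(fs, n_samples = 3)$image[1, 1]  # 7
extract_background <- function(frames, n_samples = 100, seed = 1L) {
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  stopifnot(is.list(frames))
  if (length(frames) == 0) stop("empty frame stack")
  stopifnot(n_samples >= 1)
  n <- length(frames)
  idx <- if (n_samples >= n) seq_len(n) else
    with_scene_rng(seed, function() sort(sample.int(n, n_samples)))
  d <- dim(frames[[1]])
  m <- matrix(NA_integer_, prod(d), length(idx))
  for (k in seq_along(idx))
    m[, k] <- as.integer(round(clip255(frames[[idx[k]]])))
  img <- matrix(as.numeric(.row_mode_u8(m)), d[1], d[2])
  structure(list(image = img, mean_intensity = mean(img),
                 n_samples = length(idx)),
            class = "background_plate")
}

#' @export
print.background_plate <- function(x, ...) {
  cat(sprintf("<background_plate: %d x %d px, mean %.2f, from %d frames>\n",
              dim(x$image)[2], dim(x$image)[1], x$mean_intensity, x$n_samples))
  invisible(x)
}

#' Correct global illumination drift against the background plate
#'
#' Shifts every pixel by the difference between the plate's mean intensity
#' and the frame's, so the adjusted frame has the plate's mean (up to
#' clipping at \[0, 255\]).
#'
#' @param frame Numeric matrix, same dimensions as the plate.
#' @param plate A [extract_background()] result.
#' @return The adjusted frame.
#' @export
adjust_intensity <- function(frame, plate) {
  stopifnot(inherits(plate, "background_plate"))
  if (!identical(dim(frame), dim(plate$image)))
    stop("frame and background plate dimensions differ")
  clip255(frame + (plate$mean_intensity - mean(frame)))
}

#' Background subtraction with intensity reversal
#'
#' Returns `255 - |frame - plate|`: static pixels come out near white and
#' moving flies (whose bodies differ strongly from the background) come out
#' dark, so downstream code can always assume dark flies on a light field
#' regardless of the input's polarity.
#'
#' @inheritParams adjust_intensity
#' @return Reversed difference image in \[0, 255\].
#' @export
subtract_background <- function(frame, plate) {
  stopifnot(inherits(plate, "background_plate"))
  if (!identical(dim(frame), dim(plate$image)))
    stop("frame and background plate dimensions differ")
  clip255(255 - abs(frame - plate$image))
}
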