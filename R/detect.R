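#' Laplacian-of-Gaussian blob kernel
#'
#' Evaluates
#' \deqn{LoG(x, y) = -\frac{1}{\pi\sigma^4}\left(1 - \frac{x^2+y^2}{2\sigma^2}\right)
#'   e^{-(x^2+y^2)/(2\sigma^2)}}
#' on the integer grid \eqn{[-h, h]^2}. The kernel is negative at the centre
#' with a positive annulus beyond radius \eqn{\sigma\sqrt{2}}, so convolving
#' it with an image turns dark fly bodies into bright response blobs.
#'
#' @param sigma Kernel scale \eqn{\sigma} in pixels (about the body's
#'   half-width; default 6).
#' @param half_width Half-width `h` of the grid; default `ceiling(3 * sigma)`.
#' @return A `(2h+1) x (2h+1)` matrix of class `log_kernel` with attributes
#'   `sigma` and `half_width`.
#' @export
#' @examples
#' k <- log_kernel(1)
#' k[attr(k, "half_width") + 1, attr(k, "half_width") + 1]  # -1/pi
log_kernel <- function(sigma = 6, half_width = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  h <- as.integer(half_width)
  g <- seq(-h, h)
  r2 <- outer(g^2, g^2, "+")
  k <- -(1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  structure(k, class = c("log_kernel", "matrix"),
            sigma = sigma, half_width = h)
}

# reflect-pad a matrix by `h` pixels on every side
pad_reflect <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  if (h >= nr || h >= nc) stop("kernel too large for image")
  ri <- c(rev(seq_len(h) + 1L), seq_len(nr), nr - seq_len(h))
  ci <- c(rev(seq_len(h) + 1L), seq_len(nc), nc - seq_len(h))
  m[ri, ci]
}

#' Convolve an image with a blob kernel
#'
#' 2-D convolution with reflected borders. On the reversed-difference images
#' produced by [subtract_background()] (dark flies on a light field), bodies
#' come out as bright, smooth response peaks while the flat field maps to
#' roughly zero (the kernel has near-zero DC response).
#'
#' @param image Numeric matrix.
#' @param kernel A [log_kernel()] (any odd-sized kernel matrix works).
#' @return Response matrix, same size as `image`.
#' @export
blob_filter <- function(image, kernel) {
  h <- (nrow(kernel) - 1L) %/% 2L
  padded <- pad_reflect(image, h)
  res <- EBImage::filter2(padded, unclass(kernel), boundary = "circular")
  res[(h + 1):(h + nrow(image)), (h + 1):(h + ncol(image)), drop = FALSE]
}

#' Soft-threshold a blob-response image
#'
#' Pixels below `threshold` are zeroed; pixels at or above it keep their
#' response values (this is deliberately not binary thresholding — the
#' retained intensities drive merged-blob splitting and show the "two
#' mountains" of a touching pair).
#'
#' @param filtered Response image from [blob_filter()].
#' @param threshold Response cut-off.
#' @return Nonnegative image: zero below the cut-off, original values above.
#' @export
threshold_blobs <- function(filtered, threshold) {
  out <- filtered
  out[out < max(threshold, 0)] <- 0
  out
}

new_blob <- function(pixels, values) {
  # pixels: n x 2 matrix of 0-based (x, y)
  x <- pixels[, 1]; y <- pixels[, 2]
  list(pixels = pixels,
       values = values,
       area = nrow(pixels),
       centroid = c(mean(x), mean(y)),
       bbox = c(x_min = min(x), y_min = min(y),
                width = max(x) - min(x) + 1L, height = max(y) - min(y) + 1L))
}

#' Label connected response blobs
#'
#' 8-connected components of the nonzero pixels, each measured for area,
#' bounding box, centroid (mean of member pixel coordinates) and the
#' retained response values. Components smaller than `min_area` pixels are
#' dropped as noise.
#'
#' @param blob_image Nonnegative image from [threshold_blobs()].
#' @param min_area Minimum component area in pixels.
#' @return List of blobs; each blob is a list with elements `pixels`
#'   (n x 2 matrix of 0-based (x, y)), `values`, `area`, `centroid`, `bbox`.
#' @export
label_blobs <- function(blob_image, min_area = 1) {
  if (any(blob_image < 0)) stop("blob image must be nonnegative")
  lab <- .label_cc8(blob_image)
  idx <- which(lab > 0L)
  if (length(idx) == 0) return(list())
  nr <- nrow(lab)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  labs <- lab[idx]
  vals <- blob_image[idx]
  out <- lapply(split(seq_along(idx), labs), function(ii) {
    new_blob(cbind(x = cols[ii] - 1L, y = rows[ii] - 1L), vals[ii])
  })
  out <- unname(out)
  out[vapply(out, function(b) b$area >= min_area, logical(1))]
}

#' Blob list as a tibble
#'
#' @param blobs List of blobs from [label_blobs()].
#' @return Tibble with one row per blob: `blob_id`, `x`, `y`, `area`, and
#'   bounding-box columns.
#' @export
blobs_tibble <- function(blobs) {
  if (length(blobs) == 0)
    return(tibble::tibble(blob_id = integer(), x = numeric(), y = numeric(),
                          area = integer(), bbox_x = integer(),
                          bbox_y = integer(), bbox_w = integer(),
                          bbox_h = integer()))
  tibble::tibble(
    blob_id = seq_along(blobs),
    x = vapply(blobs, function(b) b$centroid[1], numeric(1)),
    y = vapply(blobs, function(b) b$centroid[2], numeric(1)),
    area = vapply(blobs, function(b) as.integer(b$area), integer(1)),
    bbox_x = vapply(blobs, function(b) as.integer(b$bbox[1]), integer(1)),
    bbox_y = vapply(blobs, function(b) as.integer(b$bbox[2]), integer(1)),
    bbox_w = vapply(blobs, function(b) as.integer(b$bbox[3]), integer(1)),
    bbox_h = vapply(blobs, function(b) as.integer(b$bbox[4]), integer(1))
  )
}

#' Merged-blob splitting configuration
#'
#' @param base_threshold Response threshold the blob image was cut at; the
#'   escalation starts from here. If `NULL`, each blob starts from its own
#'   minimum retained value.
#' @param step_frac Threshold increment per iteration, as a fraction of the
#'   blob's response span above the base (the response scale depends on
#'   image contrast, so a relative step is used).
#' @param max_iter Maximum escalation iterations.
#' @param min_frag_frac A sub-component only counts if its area is at least
#'   this fraction of the expected single-fly area. Escalation legitimately
#'   shrinks components to their response cores, so this is only meant to
#'   ignore noise specks.
#' @return A `split_config` list.
#' @export
split_config <- function(base_threshold = NULL, step_frac = 0.05,
                         max_iter = 20, min_frag_frac = 0.05) {
  stopifnot(step_frac > 0, max_iter >= 1)
  structure(list(base_threshold = base_threshold, step_frac = step_frac,
                 max_iter = max_iter, min_frag_frac = min_frag_frac),
            class = "split_config")
}

# label the pixels of one blob at an escalated threshold; returns blobs
relabel_blob_at <- function(blob, thr) {
  keep <- blob$values >= thr
  if (!any(keep)) return(list())
  bb <- blob$bbox
  patch <- matrix(0, bb["height"], bb["width"])
  px <- blob$pixels[keep, , drop = FALSE]
  patch[cbind(px[, 2] - bb["y_min"] + 1L, px[, 1] - bb["x_min"] + 1L)] <-
    blob$values[keep]
  subs <- label_blobs(patch, min_area = 1)
  lapply(subs, function(s) {
    s$pixels[, 1] <- s$pixels[, 1] + bb["x_min"]
    s$pixels[, 2] <- s$pixels[, 2] + bb["y_min"]
    new_blob(s$pixels, s$values)
  })
}

#' Split merged multi-fly blobs by threshold escalation
#'
#' The mean blob area is taken as the expected single-fly area. Any blob
#' whose area rounds to `m > 1` expected flies is re-thresholded in place:
#' the cut-off rises by one step per iteration until the blob's own pixels
#' separate into at least `m` components (of non-trivial area) or `max_iter`
#' is reached. On success the blob is replaced by the `m` largest re-measured
#' sub-blobs; on failure (heavily overlapping flies form a single response
#' peak) the original blob is kept, to be handled as a single detection.
#'
#' @param blobs List of blobs from [label_blobs()].
#' @param cfg A [split_config()].
#' @param expected_area Expected single-fly area; default mean blob area.
#' @return List of blobs, in the original order with split results substituted.
#' @export
split_merged <- function(blobs, cfg = split_config(), expected_area = NULL) {
  if (length(blobs) == 0) return(blobs)
  if (is.null(expected_area))
    expected_area <- mean(vapply(blobs, function(b) b$area, numeric(1)))
  out <- list()
  for (b in blobs) {
    m <- max(1, round(b$area / expected_area))
    if (m == 1) { out <- c(out, list(b)); next }
    base <- if (!is.null(cfg$base_threshold)) cfg$base_threshold else
      min(b$values)
    span <- max(b$values) - base
    step <- max(cfg$step_frac * span, .Machine$double.eps * 100)
    success <- NULL
    for (i in seq_len(cfg$max_iter)) {
      thr <- base + i * step
      subs <- relabel_blob_at(b, thr)
      areas <- vapply(subs, function(s) s$area, numeric(1))
      subs <- subs[areas >= cfg$min_frag_frac * expected_area]
      if (length(subs) >= m) {
        areas <- vapply(subs, function(s) s$area, numeric(1))
        success <- subs[order(areas, decreasing = TRUE)[seq_len(m)]]
        break
      }
    }
    out <- c(out, if (is.null(success)) list(b) else success)
  }
  out
}

#' Detection configuration
#'
#' @param sigma LoG scale in pixels (see [log_kernel()]).
#' @param half_width LoG grid half-width; default `3 * sigma`.
#' @param threshold Response threshold, in LoG-response units (intensity
#'   times kernel weight). A full-contrast fly body (about 160 gray levels
#'   against the background) peaks near 1.5, while sensor-noise responses
#'   stay below about 0.1 above the field level, so the default 0.5 retains
#'   bodies with a margin; preview candidates with [threshold_preview()].
#' @param min_area Absolute minimum blob area in pixels.
#' @param min_area_frac Additional relative area filter: blobs below this
#'   fraction of the mean blob area are dropped.
#' @param split A [split_config()].
#' @param wing A [wing_search_config()].
#' @param adjust Logical: apply [adjust_intensity()] before subtraction.
#' @return A `detect_config` list.
#' @export
detect_config <- function(sigma = 6, half_width = NULL, threshold = 0.5,
                          min_area = 25, min_area_frac = 0.2,
                          split = split_config(), wing = wing_search_config(),
                          adjust = TRUE) {
  structure(list(sigma = sigma,
                 half_width = if (is.null(half_width)) ceiling(3 * sigma)
                              else half_width,
                 threshold = threshold, min_area = min_area,
                 min_area_frac = min_area_frac, split = split, wing = wing,
                 adjust = adjust),
            class = "detect_config")
}

#' Detect and measure flies in a single frame
#'
#' Runs the full per-frame chain: intensity adjustment, background
#' subtraction with reversal, LoG filtering, soft thresholding, blob
#' labelling, merged-blob splitting, then posture (ellipse + heading) for
#' every blob against the adjusted raw frame.
#'
#' @param frame Grayscale frame (numeric matrix, \[0, 255\]).
#' @param plate A [extract_background()] plate.
#' @param cfg A [detect_config()].
#' @param kernel Optional precomputed [log_kernel()] (avoids rebuilding per
#'   frame).
#' @return Tibble with one row per detection: centroid `x`, `y`, `area`,
#'   bbox columns, ellipse `a`, `b`, `theta`, and heading columns
#'   `heading_dx`, `heading_dy`, `heading_valid`.
#' @export
detect_frame <- function(frame, plate, cfg = detect_config(), kernel = NULL) {
  if (is.null(kernel)) kernel <- log_kernel(cfg$sigma, cfg$half_width)
  adj <- if (cfg$adjust) adjust_intensity(frame, plate) else frame
  fg <- subtract_background(adj, plate)
  resp <- blob_filter(fg, kernel)
  bi <- threshold_blobs(resp, cfg$threshold)
  blobs <- label_blobs(bi, min_area = cfg$min_area)
  if (length(blobs) > 1) {
    mean_area <- mean(vapply(blobs, function(b) b$area, numeric(1)))
    blobs <- blobs[vapply(blobs, function(b)
      b$area >= cfg$min_area_frac * mean_area, logical(1))]
  }
  split_cfg <- cfg$split
  if (is.null(split_cfg$base_threshold))
    split_cfg$base_threshold <- cfg$threshold
  blobs <- split_merged(blobs, split_cfg)
  if (length(blobs) == 0) return(empty_detections())
  post <- purrr::map_dfr(blobs, function(b) fit_posture(b, adj, cfg$wing))
  dplyr::bind_cols(blob_id = seq_along(blobs), post,
                   blobs_tibble(blobs)[, c("area", "bbox_x", "bbox_y",
                                           "bbox_w", "bbox_h")])
}

empty_detections <- function() {
  tibble::tibble(blob_id = integer(), x = numeric(), y = numeric(),
                 a = numeric(), b = numeric(), theta = numeric(),
                 heading_dx = numeric(), heading_dy = numeric(),
                 heading_valid = logical(), area = integer(),
                 bbox_x = integer(), bbox_y = integer(), bbox_w = integer(),
                 bbox_h = integer())
}
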