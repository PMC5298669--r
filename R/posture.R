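#' Blob centroid
#'
#' Arithmetic mean of the blob's member pixel coordinates.
#'
#' @param blob A blob from [label_blobs()].
#' @return `c(x, y)` in 0-based pixels.
#' @export
blob_centroid <- function(blob) {
  if (is.null(blob$pixels) || nrow(blob$pixels) == 0)
    stop("empty blob has no centroid")
  c(mean(blob$pixels[, 1]), mean(blob$pixels[, 2]))
}

#' Normalized second central moments of a blob
#'
#' \eqn{u_{xx} = \sum (x_i - \bar x)^2 / N + 1/12},
#' \eqn{u_{yy} = \sum (y_i - \bar y)^2 / N + 1/12},
#' \eqn{u_{xy} = \sum (x_i - \bar x)(y_i - \bar y) / N}.
#' The 1/12 term is the second central moment of a unit-length pixel, so a
#' single pixel already behaves as a unit square. No such correction applies
#' to the cross term: it would tilt every axis-aligned region, and the
#' eigen-equivalence of the ellipse fit only holds without it.
#'
#' @param blob A blob from [label_blobs()].
#' @return Named vector `c(uxx, uyy, uxy)` in pixels squared.
#' @export
second_moments <- function(blob) {
  if (is.null(blob$pixels) || nrow(blob$pixels) == 0)
    stop("empty blob has no moments")
  x <- blob$pixels[, 1]; y <- blob$pixels[, 2]
  xb <- mean(x); yb <- mean(y)
  c(uxx = mean((x - xb)^2) + 1 / 12,
    uyy = mean((y - yb)^2) + 1 / 12,
    uxy = mean((x - xb) * (y - yb)))
}

#' Best-fit ellipse from second moments
#'
#' With \eqn{\Delta = \sqrt{(u_{xx} - u_{yy})^2 + 4 u_{xy}^2}}, the full
#' major and minor axis lengths are \eqn{a = 2\sqrt2\sqrt{u_{xx}+u_{yy}+\Delta}}
#' and \eqn{b = 2\sqrt2\sqrt{u_{xx}+u_{yy}-\Delta}}; the orientation
#' \eqn{\theta \in (-\pi/2, \pi/2]} follows the half-angle rule
#' \eqn{\tan\theta = (u_{yy}-u_{xx}+\Delta)/(2u_{xy})} when \eqn{u_{yy} > u_{xx}},
#' \eqn{\tan\theta = 2u_{xy}/(u_{xx}-u_{yy}+\Delta)} otherwise, and 0 for the
#' degenerate circular case. These equal the eigen-axes of the central
#' second-moment matrix (axes \eqn{= 4\sqrt{\lambda}}, angle of the principal
#' eigenvector), measured in image coordinates (y down).
#'
#' @param moments `c(uxx, uyy, uxy)` from [second_moments()].
#' @param centroid `c(x, y)` from [blob_centroid()].
#' @return An `ellipse_fit` list: `centroid`, `uxx`, `uyy`, `uxy`, `delta`,
#'   `major` (a), `minor` (b), `theta`.
#' @export
ellipse_fit <- function(moments, centroid = c(NA_real_, NA_real_)) {
  uxx <- moments[["uxx"]]; uyy <- moments[["uyy"]]; uxy <- moments[["uxy"]]
  delta <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  a <- 2 * sqrt(2) * sqrt(max(uxx + uyy + delta, 0))
  b <- 2 * sqrt(2) * sqrt(max(uxx + uyy - delta, 0))
  # the circular case (uxy = 0 and uxx = uyy, hence uxx - uyy + delta = 0)
  # must be tested last: a vertical region also has uxy = 0 but takes the
  # first branch (atan(Inf) = pi/2)
  theta <- if (uyy > uxx) {
    atan((uyy - uxx + delta) / (2 * uxy))
  } else if (uxx > uyy || uxy != 0) {
    atan(2 * uxy / (uxx - uyy + delta))
  } else {
    0
  }
  structure(list(centroid = centroid, uxx = uxx, uyy = uyy, uxy = uxy,
                 delta = delta, major = a, minor = b, theta = theta),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit: a=%.3f b=%.3f theta=%.4f rad>\n",
              x$major, x$minor, x$theta))
  invisible(x)
}

#' Wing-search configuration for heading detection
#'
#' Wings show an intermediate intensity between body and background. A set
#' of (floor, ceiling) threshold couples band-passes the raw patch; each of
#' the two search points at the major-axis ends collects the band-passed
#' pixels within `search_radius`. A couple whose band mostly fires outside
#' both search discs ("environment pixels") is evidence of background
#' texture, not wings, and is discarded.
#'
#' @param threshold_couples `NULL` for automatic couples (see Details), or a
#'   2-column matrix of (floor, ceiling) gray levels.
#' @param n_couples Number of automatic couples tiling the intensity band
#'   between the body's 90th percentile and the local background level.
#' @param search_radius Disc radius around each search point, pixels;
#'   `NULL` scales it to 0.35 of the fitted major axis (at least 3 px).
#' @param search_offset Search points sit at centroid ± `search_offset * a`
#'   along the major axis (0.5 = the ellipse vertices).
#' @param min_score Minimum accumulated wing-pixel count for a verdict.
#' @param env_reject_ratio A couple is discarded when environment pixels
#'   exceed this fraction of all its band-passed pixels.
#' @param min_elongation Minimum `a/b` for the major axis (and thus heading)
#'   to be considered defined.
#'
#' @details Automatic couples: the band runs from just above the blob's dark
#' body level (its 10th-percentile raw intensity, pushed 10% of the way
#' toward the background) to just below the local background level (the
#' patch's 75th-percentile intensity minus 5); `n_couples` windows of width
#' `max(10, band/n_couples)` are equally spaced across it.
#' @return A `wing_search_config` list.
#' @export
wing_search_config <- function(threshold_couples = NULL, n_couples = 6,
                               search_radius = NULL, search_offset = 0.5,
                               min_score = 3, env_reject_ratio = 0.5,
                               min_elongation = 1.1) {
  if (!is.null(threshold_couples)) {
    threshold_couples <- as.matrix(threshold_couples)
    stopifnot(ncol(threshold_couples) == 2,
              all(threshold_couples[, 1] < threshold_couples[, 2]))
  }
  structure(list(threshold_couples = threshold_couples,
                 n_couples = n_couples, search_radius = search_radius,
                 search_offset = search_offset, min_score = min_score,
                 env_reject_ratio = env_reject_ratio,
                 min_elongation = min_elongation),
            class = "wing_search_config")
}

auto_couples <- function(body_vals, patch_vals, n) {
  # The blob's pixel support (LoG response support) spills past the body, so
  # anchor on its dark decile — the body proper — and the patch's bright
  # quartile — the local background — and tile the band in between.
  body_lo <- unname(quantile(body_vals, 0.1))
  hi <- unname(quantile(patch_vals, 0.75)) - 5
  lo <- body_lo + 0.1 * (hi - body_lo)
  if (hi - lo < 4) return(NULL)
  w <- max(10, (hi - lo) / n)
  floors <- seq(lo, hi - w, length.out = n)
  cbind(floor = floors, ceiling = floors + w)
}

#' Signed heading direction from wing-pixel scoring
#'
#' Places two search points at the ends of the fitted major axis and scores
#' each across the threshold couples; the higher-scoring point (if its score
#' exceeds `min_score`) marks the wings, and the heading points from the
#' centroid toward the opposite end. Ties, sub-threshold scores, or a
#' near-circular fit give `valid = FALSE` — the tracker treats such headings
#' as unavailable rather than guessing.
#'
#' @param blob A blob from [label_blobs()].
#' @param fit Its [ellipse_fit()].
#' @param frame The raw (adjusted) grayscale frame — not the LoG response;
#'   wing pixels only exist in the original intensities.
#' @param cfg A [wing_search_config()].
#' @return A `heading_result` list: `direction` (unit `c(dx, dy)` or `NA`),
#'   `head_point`, `tail_point`, `score_head_end`, `score_tail_end`,
#'   `valid`.
#' @export
heading_direction <- function(blob, fit, frame, cfg = wing_search_config()) {
  fail <- function(p1 = c(NA_real_, NA_real_), p2 = c(NA_real_, NA_real_),
                   s1 = 0, s2 = 0) {
    structure(list(direction = c(NA_real_, NA_real_), head_point = p1,
                   tail_point = p2, score_head_end = s1, score_tail_end = s2,
                   valid = FALSE), class = "heading_result")
  }
  if (fit$minor <= 0 || fit$major / fit$minor < cfg$min_elongation)
    return(fail())
  u <- c(cos(fit$theta), sin(fit$theta))
  ctr <- fit$centroid
  p1 <- ctr + cfg$search_offset * fit$major * u   # "+theta" end
  p2 <- ctr - cfg$search_offset * fit$major * u
  r <- if (is.null(cfg$search_radius)) max(3, 0.35 * fit$major)
       else cfg$search_radius

  # raw patch: bbox expanded to cover both search discs
  d <- dim(frame)
  bb <- blob$bbox
  x0 <- max(0, floor(min(bb["x_min"], p1[1] - r, p2[1] - r)) - 1)
  y0 <- max(0, floor(min(bb["y_min"], p1[2] - r, p2[2] - r)) - 1)
  x1 <- min(d[2] - 1, ceiling(max(bb["x_min"] + bb["width"] - 1,
                                  p1[1] + r, p2[1] + r)) + 1)
  y1 <- min(d[1] - 1, ceiling(max(bb["y_min"] + bb["height"] - 1,
                                  p1[2] + r, p2[2] + r)) + 1)
  patch <- frame[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  px <- rep(x0:x1, each = nrow(patch))
  py <- rep(y0:y1, times = ncol(patch))
  v <- as.vector(patch)

  couples <- cfg$threshold_couples
  if (is.null(couples)) {
    body_vals <- frame[cbind(blob$pixels[, 2] + 1L, blob$pixels[, 1] + 1L)]
    couples <- auto_couples(body_vals, v, cfg$n_couples)
    if (is.null(couples)) return(fail(p1, p2))
  }

  d1 <- (px - p1[1])^2 + (py - p1[2])^2 <= r^2
  d2 <- (px - p2[1])^2 + (py - p2[2])^2 <= r^2
  s1 <- 0; s2 <- 0
  for (k in seq_len(nrow(couples))) {
    marked <- v >= couples[k, 1] & v < couples[k, 2]
    tot <- sum(marked)
    if (tot == 0) next
    in1 <- sum(marked & d1); in2 <- sum(marked & d2)
    env <- tot - sum(marked & (d1 | d2))
    if (env > cfg$env_reject_ratio * tot) next
    s1 <- s1 + in1; s2 <- s2 + in2
  }
  if (max(s1, s2) <= cfg$min_score || s1 == s2) return(fail(p1, p2, s1, s2))
  # higher score marks the wings (the tail); head is the other end
  if (s1 > s2) {
    head_pt <- p2; tail_pt <- p1; dir <- -u
  } else {
    head_pt <- p1; tail_pt <- p2; dir <- u
  }
  structure(list(direction = dir, head_point = head_pt, tail_point = tail_pt,
                 score_head_end = min(s1, s2), score_tail_end = max(s1, s2),
                 valid = TRUE), class = "heading_result")
}

#' Full posture for one blob
#'
#' Centroid, ellipse and heading in one call.
#'
#' @inheritParams heading_direction
#' @param cfg A [wing_search_config()].
#' @return One-row tibble: `x`, `y`, `a`, `b`, `theta`, `heading_dx`,
#'   `heading_dy`, `heading_valid`.
#' @export
fit_posture <- function(blob, frame, cfg = wing_search_config()) {
  ctr <- blob_centroid(blob)
  fit <- ellipse_fit(second_moments(blob), ctr)
  hd <- heading_direction(blob, fit, frame, cfg)
  tibble::tibble(x = ctr[1], y = ctr[2], a = fit$major, b = fit$minor,
                 theta = fit$theta,
                 heading_dx = hd$direction[1], heading_dy = hd$direction[2],
                 heading_valid = hd$valid)
}
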