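#' Detect flies on every frame of a video
#'
#' Phase one of the two-phase workflow: the background plate is extracted
#' once, then every frame is run through [detect_frame()]. The result can be
#' persisted and re-tracked many times with different tracking settings
#' without re-detection.
#'
#' @param input A [frame_stack()] or a directory of numbered PNG frames.
#' @param cfg A [detect_config()].
#' @param frames Optional integer vector restricting the frame range.
#' @param n_samples,seed Background sampling controls (see
#'   [extract_background()]).
#' @param out Optional output directory; if given, writes `detections.csv`
#'   and `manifest.json` there.
#' @param fps Frame rate override when reading from a directory.
#' @return A tibble of detections with a `frame` column prepended (class
#'   `flytrax_detections`), with the background plate in attribute `plate`.
#' @export
detect_all <- function(input, cfg = detect_config(), frames = NULL,
                       n_samples = 100, seed = 1L, out = NULL, fps = 20) {
  stack <- if (is.character(input)) read_frames(input, fps = fps) else input
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(frames)) frames <- seq_along(stack$frames)
  stopifnot(all(frames >= 1), all(frames <= length(stack$frames)))
  plate <- extract_background(stack$frames[frames], n_samples = n_samples,
                              seed = seed)
  kernel <- log_kernel(cfg$sigma, cfg$half_width)
  dets <- purrr::map_dfr(frames, function(f) {
    d <- detect_frame(stack$frames[[f]], plate, cfg, kernel)
    if (nrow(d) == 0) return(d)
    dplyr::bind_cols(frame = f, d)
  })
  if (nrow(dets) == 0)
    dets <- dplyr::bind_cols(frame = integer(), empty_detections())
  class(dets) <- c("flytrax_detections", class(dets))
  attr(dets, "plate") <- plate
  attr(dets, "fps") <- stack$fps
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    readr::write_csv(dets, file.path(out, "detections.csv"))
    write_manifest(file.path(out, "manifest.json"), cfg, seed,
                   length(frames), stack$fps)
  }
  dets
}

write_manifest <- function(path, cfg, seed, n_frames, fps) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else
    unclass(x)
  cfg_plain <- strip(cfg)
  jsonlite::write_json(list(
    software = "flytrax",
    version = as.character(utils::packageVersion("flytrax")),
    seed = seed, n_frames = n_frames, fps = fps,
    frame_interval_s = round(frame_interval(fps), 4),
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Preview blob counts across candidate thresholds
#'
#' Helps choose the detection threshold: runs the filter once on one frame
#' and reports how many blobs each candidate threshold yields.
#'
#' @param frame A grayscale frame.
#' @param plate Background plate.
#' @param cfg A [detect_config()] (its `threshold` is ignored).
#' @param thresholds Numeric vector of candidate thresholds.
#' @return Tibble with columns `threshold`, `n_blobs`.
#' @export
threshold_preview <- function(frame, plate, cfg = detect_config(),
                              thresholds = seq(0.2, 1.4, by = 0.1)) {
  adj <- if (cfg$adjust) adjust_intensity(frame, plate) else frame
  resp <- blob_filter(subtract_background(adj, plate),
                      log_kernel(cfg$sigma, cfg$half_width))
  tibble::tibble(
    threshold = thresholds,
    n_blobs = vapply(thresholds, function(th) {
      length(label_blobs(threshold_blobs(resp, th), cfg$min_area))
    }, integer(1))
  )
}

#' Score tracked trajectories against ground truth
#'
#' Each trajectory point is associated with the nearest ground-truth fly
#' within `match_radius`. Identity swaps are transitions of a track's
#' associated fly between two (different) real flies, counted only over
#' confident frames — frames where the second-nearest fly is also within
#' `match_radius` are ambiguous (flies in close contact) and are excluded,
#' mirroring how a human scorer attributes identities only after the flies
#' separate. An identity is counted lost when a replacement track has to be
#' born after the first frame; a track mostly associated with no fly at all
#' is a false positive.
#'
#' @param tracking A `flytrax_tracking` object or trajectory tibble.
#' @param truth Ground-truth tibble from [simulate_motion()].
#' @param match_radius Association radius in pixels (about one body length).
#' @return One-row tibble: `n_ids`, `swaps`, `losses`, `false_positives`,
#'   `mean_position_error`, `coverage` (fraction of (frame, fly) ground
#'   truth points claimed by some track).
#' @export
evaluate_tracks <- function(tracking, truth, match_radius = 10) {
  traj <- if (inherits(tracking, "flytrax_tracking")) tracking$trajectories
          else tracking
  if (nrow(traj) == 0)
    return(tibble::tibble(n_ids = 0L, swaps = 0L, losses = 0L,
                          false_positives = 0L,
                          mean_position_error = NA_real_, coverage = 0))
  first_frame <- min(traj$frame)
  assoc <- traj |>
    dplyr::left_join(truth[, c("frame", "fly", "x", "y")], by = "frame",
                     suffix = c("", "_true"), relationship = "many-to-many") |>
    dplyr::mutate(dist = sqrt((.data$x - .data$x_true)^2 +
                              (.data$y - .data$y_true)^2)) |>
    dplyr::group_by(.data$frame, .data$id) |>
    dplyr::arrange(.data$dist, .by_group = TRUE) |>
    dplyr::summarise(fly = .data$fly[1],
                     dist2 = if (dplyr::n() > 1) .data$dist[2] else Inf,
                     dist = .data$dist[1],
                     .groups = "drop") |>
    dplyr::mutate(confident = .data$dist <= match_radius &
                    .data$dist2 > match_radius,
                  fly = ifelse(.data$dist <= match_radius, .data$fly, NA))

  per_id <- assoc |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      swaps = {
        f <- .data$fly[!is.na(.data$fly) & .data$confident]
        if (length(f) < 2) 0L else sum(diff(f) != 0)
      },
      born = min(.data$frame),
      assigned_frac = mean(!is.na(.data$fly)),
      .groups = "drop"
    )
  fp <- per_id$assigned_frac < 0.5
  tibble::tibble(
    n_ids = nrow(per_id),
    swaps = sum(per_id$swaps),
    losses = sum(per_id$born > first_frame & !fp),
    false_positives = sum(fp),
    mean_position_error = mean(assoc$dist[!is.na(assoc$fly)]),
    coverage = {
      claimed <- assoc[!is.na(assoc$fly), c("frame", "fly")]
      nrow(dplyr::distinct(claimed)) /
        nrow(dplyr::distinct(truth[, c("frame", "fly")]))
    }
  )
}

# ---- pixel-level overlay drawing (device-free, deterministic) ----

draw_line_px <- function(img, p0, p1, value) {
  n <- max(2, ceiling(max(abs(p1 - p0))) + 1)
  xs <- round(seq(p0[1], p1[1], length.out = n)) + 1L
  ys <- round(seq(p0[2], p1[2], length.out = n)) + 1L
  keep <- xs >= 1 & xs <= ncol(img) & ys >= 1 & ys <= nrow(img)
  img[cbind(ys[keep], xs[keep])] <- value
  img
}

digit_font <- function() {
  # 3x5 bitmaps, rows top to bottom
  strsplit(c("111101101101111", "010110010010111", "111001111100111",
             "111001111001111", "101101111001001", "111100111001111",
             "111100111101111", "111001001001001", "111101111101111",
             "111101111001111"), "")
}

draw_label_px <- function(img, pos, label, value) {
  font <- digit_font()
  x0 <- round(pos[1]); y0 <- round(pos[2])
  for (ci in seq_len(nchar(label))) {
    d <- as.integer(substr(label, ci, ci))
    bits <- font[[d + 1]]
    for (k in seq_along(bits)) {
      if (bits[k] == "1") {
        px <- x0 + (ci - 1) * 4 + (k - 1) %% 3 + 1L
        py <- y0 + (k - 1) %/% 3 + 1L
        if (px >= 1 && px <= ncol(img) && py >= 1 && py <= nrow(img))
          img[py, px] <- value
      }
    }
  }
  img
}

#' Render an annotated overlay video
#'
#' Draws, for every frame, each live identity's label, its heading as an
#' arrow, and its trailing trajectory over the last `trail` frames, directly
#' into the pixel data (white trails/arrows, black labels). With no
#' trajectories the frames pass through unchanged.
#'
#' @param stack The input [frame_stack()].
#' @param tracking A `flytrax_tracking` object or trajectory tibble.
#' @param dir Optional output directory for numbered PNGs.
#' @param trail Number of trailing inter-frame segments to draw.
#' @param arrow_len Heading arrow length in pixels.
#' @return Invisibly, a list with `stack` (annotated [frame_stack()]) and
#'   `meta` (tibble: `frame`, `id`, `n_segments` drawn).
#' @export
render_overlay <- function(stack, tracking, dir = NULL, trail = 6,
                           arrow_len = 12) {
  traj <- if (inherits(tracking, "flytrax_tracking")) tracking$trajectories
          else tracking
  frames <- stack$frames
  meta <- list()
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    rows <- traj[traj$frame == f, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      id <- rows$id[r]
      hist <- traj[traj$id == id & traj$frame <= f &
                   traj$frame >= f - trail, , drop = FALSE]
      hist <- hist[order(hist$frame), , drop = FALSE]
      nseg <- max(0, nrow(hist) - 1)
      if (nseg > 0) {
        for (s in seq_len(nseg)) {
          img <- draw_line_px(img, c(hist$x[s], hist$y[s]),
                              c(hist$x[s + 1], hist$y[s + 1]), 255)
        }
      }
      p <- c(rows$x[r], rows$y[r])
      if (!is.na(rows$heading_angle[r])) {
        u <- c(cos(rows$heading_angle[r]), sin(rows$heading_angle[r]))
        tip <- p + arrow_len * u
        img <- draw_line_px(img, p, tip, 255)
        for (w in c(-1, 1)) {  # arrow head
          ang <- rows$heading_angle[r] + pi + w * 0.5
          img <- draw_line_px(img, tip,
                              tip + 4 * c(cos(ang), sin(ang)), 255)
        }
      }
      img <- draw_label_px(img, p + c(4, 4), as.character(id), 0)
      meta[[length(meta) + 1]] <- tibble::tibble(frame = f, id = id,
                                                 n_segments = nseg)
    }
    frames[[f]] <- img
  }
  out <- frame_stack(frames, fps = stack$fps)
  if (!is.null(dir)) write_frames(out, dir)
  invisible(list(stack = out,
                 meta = dplyr::bind_rows(meta)))
}
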