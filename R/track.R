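#' Tracking configuration
#'
#' @param gate Plausible per-frame association distance, pixels; the dummy
#'   cost is `dummy_cost_factor * gate`, so pairs farther than that prefer
#'   to stay unmatched.
#' @param dummy_cost_factor Multiplier on `gate` giving the dummy cost.
#' @param heading_tolerance_deg Largest angle (degrees) between a tracker's
#'   stored heading and a detection's heading for the pair to pass the
#'   heading confirmation gate.
#' @param max_missed Consecutive unmatched frames before a tracker retires.
#' @param q_accel_sd White-acceleration SD (px/frame^2) behind the process
#'   noise Q. Small values smooth aggressively; large values adapt faster to
#'   manoeuvres at the price of noisier position and velocity estimates. The
#'   default 0.1 keeps filtered positions and velocities well inside the
#'   measurement noise for near-constant-velocity walking; jumps are instead
#'   absorbed by the association gate.
#' @param r_sd Measurement noise SD (px) behind R.
#' @param v0_var Initial velocity variance for newborn trackers (velocity
#'   itself starts at zero).
#' @param use_heading_gate Set `FALSE` to ablate the heading confirmation
#'   (Hungarian-only association).
#' @param share_oversized When an unsplittable merged blob yields one
#'   oversized detection with two or more trackers nearby, let those
#'   trackers share it: none update from the merged centroid (its position
#'   belongs to no single fly), all coast on prediction without aging their
#'   missed counters, and the detection spawns no new identity. The flies
#'   re-separate with each identity still alive on its own path.
#' @param oversized_frac A detection is oversized when its area is at least
#'   this multiple of the frame's median detection area. Overlapping pairs
#'   shadow each other, so a merged blob can fall well short of twice the
#'   single-fly area.
#' @param fps Frame rate used to report velocities in px/s.
#' @return A `track_config` list.
#' @export
track_config <- function(gate = 50, dummy_cost_factor = 1.5,
                         heading_tolerance_deg = 90, max_missed = 10,
                         q_accel_sd = 0.1, r_sd = 2, v0_var = 25,
                         use_heading_gate = TRUE, share_oversized = TRUE,
                         oversized_frac = 1.3, fps = 20) {
  structure(list(gate = gate, dummy_cost_factor = dummy_cost_factor,
                 heading_tolerance_deg = heading_tolerance_deg,
                 max_missed = max_missed, q_accel_sd = q_accel_sd,
                 r_sd = r_sd, v0_var = v0_var,
                 use_heading_gate = use_heading_gate,
                 share_oversized = share_oversized,
                 oversized_frac = oversized_frac, fps = fps),
            class = "track_config")
}

# TRUE for each tracker whose predicted position lies within a detection's
# extent (major axis, or half the gate when unmeasured): such a tracker is
# plausibly occluded inside that blob and should not age toward retirement
occluded_trackers <- function(pred_pos, detections, gate) {
  nd <- nrow(detections)
  occ <- rep(FALSE, nrow(pred_pos))
  if (nd == 0) return(occ)
  radius <- if ("a" %in% names(detections))
    pmax(1.5 * detections$a, 6) else rep(gate / 4, nd)
  for (j in seq_len(nd)) {
    d <- sqrt((pred_pos[, 1] - detections$x[j])^2 +
              (pred_pos[, 2] - detections$y[j])^2)
    occ <- occ | d <= radius[j]
  }
  occ
}

#' Create a tracker for a newborn identity
#'
#' State is `(x, y, vx, vy)` with velocity initially zero; position variance
#' starts at the measurement variance.
#'
#' @param id Integer identity label.
#' @param pos `c(x, y)` of the spawning detection.
#' @param heading Unit heading vector, or `NULL` when unavailable.
#' @param cfg A [track_config()].
#' @return A `fly_tracker` list.
#' @export
tracker_init <- function(id, pos, heading = NULL, cfg = track_config()) {
  structure(list(id = as.integer(id),
                 state = c(pos[1], pos[2], 0, 0),
                 cov = diag(c(cfg$r_sd^2, cfg$r_sd^2, cfg$v0_var, cfg$v0_var)),
                 heading = heading, age = 0L, missed = 0L, matched = TRUE),
            class = "fly_tracker")
}

kf_transition <- function(dt) {
  matrix(c(1, 0, 0, 0,
           0, 1, 0, 0,
           dt, 0, 1, 0,
           0, dt, 0, 1), 4, 4)
}

kf_process_noise <- function(dt, q_accel_sd) {
  q <- q_accel_sd^2
  q11 <- dt^4 / 4; q13 <- dt^3 / 2; q33 <- dt^2
  q * matrix(c(q11, 0, q13, 0,
               0, q11, 0, q13,
               q13, 0, q33, 0,
               0, q13, 0, q33), 4, 4)
}

#' Kalman prediction step
#'
#' Constant-velocity model: position advances by `dt` times velocity, the
#' velocity is carried over, and the covariance inflates by the process
#' noise.
#'
#' @param t A `fly_tracker`.
#' @param dt Time step (frames; the filter works in px/frame internally).
#' @param q_accel_sd White-acceleration SD for the process noise.
#' @return The tracker with predicted state and covariance.
#' @export
kf_predict <- function(t, dt = 1, q_accel_sd = 0.1) {
  A <- kf_transition(dt)
  t$state <- as.vector(A %*% t$state)
  t$cov <- A %*% t$cov %*% t(A) + kf_process_noise(dt, q_accel_sd)
  t
}

#' Kalman correction step
#'
#' Standard update with the observation picking out `(x, y)`. The posterior
#' position lies between prediction and measurement; the covariance never
#' grows.
#'
#' @param t A `fly_tracker` (after [kf_predict()]).
#' @param z `c(x, y)` measured position.
#' @param r_sd Measurement noise SD in pixels.
#' @return The corrected tracker.
#' @export
kf_update <- function(t, z, r_sd = 2) {
  H <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4)
  R <- diag(r_sd^2, 2)
  S <- H %*% t$cov %*% t(H) + R
  K <- t$cov %*% t(H) %*% solve(S)
  t$state <- as.vector(t$state + K %*% (z - H %*% t$state))
  P <- (diag(4) - K %*% H) %*% t$cov
  t$cov <- (P + t(P)) / 2
  t
}

#' Heading confirmation of assigned pairs
#'
#' For each worker/job pair, the absolute angle between the tracker's stored
#' heading and the detection's heading is compared with `tolerance`; larger
#' angles reject the pair. A pair where either heading is unavailable is
#' accepted — heading is confirmatory evidence, not a requirement. (Pairs
#' involving dummies never reach here: they are already reported unmatched
#' and rejoin the rejected pool in [track_step()].)
#'
#' @param assignment An `assignment` from [hungarian_assign()].
#' @param tracker_headings List of unit vectors (or `NULL`s), one per worker.
#' @param detection_headings List of unit vectors (or `NULL`s), one per job.
#' @param tolerance Largest accepted angle, radians.
#' @return List with tibbles `accepted` and `rejected` (subsets of
#'   `assignment$pairs`).
#' @export
heading_check <- function(assignment, tracker_headings, detection_headings,
                          tolerance = pi / 2) {
  pairs <- assignment$pairs
  if (nrow(pairs) == 0)
    return(list(accepted = pairs, rejected = pairs))
  ok <- vapply(seq_len(nrow(pairs)), function(k) {
    ht <- tracker_headings[[pairs$worker[k]]]
    hd <- detection_headings[[pairs$job[k]]]
    if (is.null(ht) || is.null(hd) || anyNA(ht) || anyNA(hd)) return(TRUE)
    ang <- acos(pmin(pmax(sum(ht * hd), -1), 1))
    ang <= tolerance
  }, logical(1))
  list(accepted = pairs[ok, , drop = FALSE],
       rejected = pairs[!ok, , drop = FALSE])
}

det_headings_list <- function(detections) {
  lapply(seq_len(nrow(detections)), function(k) {
    if (isTRUE(detections$heading_valid[k]))
      c(detections$heading_dx[k], detections$heading_dy[k])
    else NULL
  })
}

#' One tracking step
#'
#' Advances all trackers one frame against the detections of that frame:
#' predict; Hungarian assignment of predicted positions to detections on a
#' dummy-padded distance matrix; heading confirmation of the assigned pairs;
#' closest-neighbor reassignment of the rejected pool using the trackers'
#' pre-prediction positions; Kalman update of matched trackers; coasting,
#' births, and retirements.
#'
#' @param trackers List of `fly_tracker`s.
#' @param detections Tibble with columns `x`, `y`, `heading_dx`,
#'   `heading_dy`, `heading_valid` (one row per detection; may be empty).
#' @param cfg A [track_config()].
#' @param next_id Next identity label to hand out.
#' @return List with `trackers` (updated list) and `next_id`.
#' @export
track_step <- function(trackers, detections, cfg = track_config(),
                       next_id = NULL) {
  if (is.null(next_id))
    next_id <- if (length(trackers) == 0) 1L else
      max(vapply(trackers, function(t) t$id, integer(1))) + 1L
  nd <- if (is.null(detections)) 0L else nrow(detections)
  det_h <- if (nd > 0) det_headings_list(detections) else list()

  if (length(trackers) == 0) {
    new <- lapply(seq_len(nd), function(k) {
      tracker_init(next_id + k - 1L,
                   c(detections$x[k], detections$y[k]), det_h[[k]], cfg)
    })
    return(list(trackers = new, next_id = next_id + nd))
  }

  pre_pos <- t(vapply(trackers, function(t) t$state[1:2], numeric(2)))
  predicted <- lapply(trackers, kf_predict, dt = 1,
                      q_accel_sd = cfg$q_accel_sd)
  pred_pos <- t(vapply(predicted, function(t) t$state[1:2], numeric(2)))

  matched_det <- rep(NA_integer_, length(trackers))  # det index per tracker
  shared_trk <- rep(FALSE, length(trackers))
  shared_det <- rep(FALSE, nd)
  if (nd > 1 && isTRUE(cfg$share_oversized) && "area" %in% names(detections)) {
    med_area <- stats::median(detections$area)
    for (j in seq_len(nd)) {
      if (detections$area[j] < cfg$oversized_frac * med_area) next
      radius <- if ("a" %in% names(detections))
        max(detections$a[j], 2 * cfg$r_sd) else cfg$gate / 2
      near <- which(sqrt((pred_pos[, 1] - detections$x[j])^2 +
                         (pred_pos[, 2] - detections$y[j])^2) <= radius)
      if (length(near) >= 2) {
        shared_det[j] <- TRUE
        shared_trk[near] <- TRUE
      }
    }
  }

  live_trk <- which(!shared_trk)
  live_det <- which(!shared_det)
  if (length(live_det) > 0 && length(live_trk) > 0) {
    det_pos <- cbind(detections$x, detections$y)[live_det, , drop = FALSE]
    live_det_h <- det_h[live_det]
    live_pred <- pred_pos[live_trk, , drop = FALSE]
    live_pre <- pre_pos[live_trk, , drop = FALSE]
    dummy <- cfg$dummy_cost_factor * cfg$gate
    cm <- cost_matrix(dist_xy(live_pred, det_pos), dummy_cost = dummy)
    as1 <- hungarian_assign(cm)
    if (cfg$use_heading_gate) {
      trk_h <- lapply(trackers[live_trk], function(t) t$heading)
      hc <- heading_check(as1, trk_h, live_det_h,
                          cfg$heading_tolerance_deg * pi / 180)
      accepted <- hc$accepted
      pool_w <- sort(c(hc$rejected$worker, as1$unmatched_workers))
      pool_j <- sort(c(hc$rejected$job, as1$unmatched_jobs))
    } else {
      accepted <- as1$pairs
      pool_w <- as1$unmatched_workers
      pool_j <- as1$unmatched_jobs
    }
    matched_det[live_trk[accepted$worker]] <- live_det[accepted$job]
    if (length(pool_w) > 0 && length(pool_j) > 0) {
      # rejected pairs retry with the ORIGINAL (pre-prediction) positions:
      # a fly that doubled back is closer to where it was than to where the
      # constant-velocity model sent it
      cm2 <- cost_matrix(dist_xy(live_pre[pool_w, , drop = FALSE],
                                 det_pos[pool_j, , drop = FALSE]),
                         dummy_cost = dummy)
      as2 <- closest_neighbor_assign(cm2)
      if (nrow(as2$pairs) > 0)
        matched_det[live_trk[pool_w[as2$pairs$worker]]] <-
          live_det[pool_j[as2$pairs$job]]
    }
  }

  occluded <- if (nd > 0) occluded_trackers(pred_pos, detections, cfg$gate)
              else rep(FALSE, length(trackers))
  out <- vector("list", length(trackers))
  for (i in seq_along(trackers)) {
    tr <- predicted[[i]]
    j <- matched_det[i]
    if (!is.na(j)) {
      tr <- kf_update(tr, c(detections$x[j], detections$y[j]), cfg$r_sd)
      if (!is.null(det_h[[j]])) tr$heading <- det_h[[j]]
      tr$missed <- 0L
      tr$matched <- TRUE
    } else {
      # trackers sharing a merged detection, or sitting inside some blob's
      # extent, coast without aging toward retirement
      if (!shared_trk[i] && !occluded[i]) tr$missed <- tr$missed + 1L
      tr$matched <- FALSE
    }
    tr$age <- tr$age + 1L
    out[[i]] <- tr
  }
  out <- out[vapply(out, function(t) t$missed <= cfg$max_missed, logical(1))]

  unmatched_j <- setdiff(which(!shared_det), matched_det[!is.na(matched_det)])
  for (j in unmatched_j) {
    out <- c(out, list(tracker_init(next_id,
                                    c(detections$x[j], detections$y[j]),
                                    det_h[[j]], cfg)))
    next_id <- next_id + 1L
  }
  list(trackers = out, next_id = next_id)
}

#' Track detections across all frames
#'
#' Folds [track_step()] over the frames of a detection table (the output of
#' [detect_all()] or a CSV written by it). Tracking never touches pixel
#' data, so the same detections can be re-tracked under different settings.
#'
#' @param detections Detection tibble with a `frame` column, or path to a
#'   detections CSV.
#' @param cfg A [track_config()].
#' @param frames Optional integer vector of frames to process; default is
#'   `1:max(frame)` (frames without detections coast the trackers).
#' @return A `flytrax_tracking` object: list with `trajectories` (tibble:
#'   `frame`, `id`, `x`, `y`, `vx`, `vy` in px/s, `heading_angle`,
#'   `matched`), `cfg`, `fps`, `n_frames`.
#' @export
track_all <- function(detections, cfg = track_config(), frames = NULL) {
  if (is.character(detections))
    detections <- readr::read_csv(detections, show_col_types = FALSE)
  if (is.null(frames)) {
    frames <- if (nrow(detections) > 0) seq_len(max(detections$frame)) else
      integer()
  }
  trackers <- list(); next_id <- 1L
  recs <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    dets <- detections[detections$frame == f, , drop = FALSE]
    st <- track_step(trackers, dets, cfg, next_id)
    trackers <- st$trackers; next_id <- st$next_id
    if (length(trackers) > 0) {
      recs[[fi]] <- tibble::tibble(
        frame = f,
        id = vapply(trackers, function(t) t$id, integer(1)),
        x = vapply(trackers, function(t) t$state[1], numeric(1)),
        y = vapply(trackers, function(t) t$state[2], numeric(1)),
        vx = vapply(trackers, function(t) t$state[3], numeric(1)) * cfg$fps,
        vy = vapply(trackers, function(t) t$state[4], numeric(1)) * cfg$fps,
        heading_angle = vapply(trackers, function(t) {
          if (is.null(t$heading)) NA_real_ else
            atan2(t$heading[2], t$heading[1])
        }, numeric(1)),
        matched = vapply(trackers, function(t) isTRUE(t$matched), logical(1))
      )
    }
  }
  traj <- dplyr::bind_rows(recs)
  if (nrow(traj) > 0) traj <- dplyr::arrange(traj, .data$frame, .data$id)
  structure(list(trajectories = traj, cfg = cfg, fps = cfg$fps,
                 n_frames = length(frames)),
            class = "flytrax_tracking")
}

#' @export
print.flytrax_tracking <- function(x, ...) {
  cat(sprintf("<flytrax_tracking: %d frames, %d identities, dt = %.4f s>\n",
              x$n_frames,
              dplyr::n_distinct(x$trajectories$id),
              frame_interval(x$fps)))
  invisible(x)
}

#' @rdname track_all
#' @param x A `flytrax_tracking` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.flytrax_tracking <- function(x, ...) x$trajectories

#' @rdname track_all
#' @exportS3Method generics::glance
glance.flytrax_tracking <- function(x, ...) {
  tr <- x$trajectories
  tibble::tibble(
    n_frames = x$n_frames,
    n_identities = dplyr::n_distinct(tr$id),
    dt = frame_interval(x$fps),
    mean_speed = if (nrow(tr) > 0) mean(sqrt(tr$vx^2 + tr$vy^2)) else NA_real_,
    match_rate = if (nrow(tr) > 0) mean(tr$matched) else NA_real_
  )
}
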