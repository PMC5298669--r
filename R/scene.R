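#' Synthetic arena scene specification
#'
#' Describes a circular arena filmed from above with dark flies on a brighter
#' floor, the setting the detector and tracker are built for. Bodies are
#' filled ellipses at `body_level`; wings trail behind the head at
#' `wing_level`, an intensity strictly between body and background, which is
#' what the heading-direction search exploits. The defaults emulate a small
#' arena at 20 fps with per-fly walk speeds around 40 px/s, inside the range
#' of average speeds reported for walking-fly arena videos (roughly 13-94
#' px/s at ~20 fps).
#'
#' Angles are in radians, zero along +x, counter-clockwise positive in the
#' (x, y) pixel frame; note the image y axis points down.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param arena_center,arena_radius Arena disc (pixels); flies stay inside.
#' @param background_level,body_level,wing_level Gray levels in \[0, 255\]
#'   with `body_level < wing_level < background_level`.
#' @param n_flies Number of flies.
#' @param body_axes `c(semi_major, semi_minor)` of the body ellipse, pixels.
#' @param fps Frame rate, frames/second.
#' @param n_frames Number of frames to simulate.
#' @param illumination_drift Added gray levels per frame (slow lighting
#'   drift; 0 disables).
#' @param noise_sd SD of per-pixel Gaussian noise (gray levels).
#' @param walk_speed Mean walking step, px/frame.
#' @param turn_sd SD of the per-frame heading increment, radians.
#' @param jump_prob Per-fly per-frame probability of a jump.
#' @param jump_range Jump length range in multiples of `walk_speed`.
#' @param min_separation Minimum centre-to-centre distance enforced between
#'   flies outside scripted crossings, pixels.
#' @param rng_seed Integer seed making motion and rendering reproducible.
#'
#' @return An object of class `scene_spec` (a list of the above).
#' @export
#' @examples
#' spec <- scene_spec(n_flies = 3, n_frames = 10)
#' spec$body_axes
scene_spec <- function(image_size = c(240, 240),
                       arena_center = c(119.5, 119.5),
                       arena_radius = 105,
                       background_level = 200,
                       body_level = 40,
                       wing_level = 140,
                       n_flies = 10,
                       body_axes = c(8, 3),
                       fps = 20,
                       n_frames = 100,
                       illumination_drift = 0,
                       noise_sd = 2,
                       walk_speed = 2,
                       turn_sd = 0.25,
                       jump_prob = 0.005,
                       jump_range = c(5, 15),
                       min_separation = 4 * body_axes[1],
                       rng_seed = 1L) {
  stopifnot(body_level < wing_level, wing_level < background_level,
            fps > 0, n_frames >= 1, body_axes[1] >= body_axes[2],
            arena_radius > 4 * body_axes[1], n_flies >= 0)
  structure(list(
    image_size = image_size, arena_center = arena_center,
    arena_radius = arena_radius, background_level = background_level,
    body_level = body_level, wing_level = wing_level, n_flies = n_flies,
    body_axes = body_axes, fps = fps, n_frames = n_frames,
    illumination_drift = illumination_drift, noise_sd = noise_sd,
    walk_speed = walk_speed, turn_sd = turn_sd, jump_prob = jump_prob,
    jump_range = jump_range, min_separation = min_separation,
    rng_seed = as.integer(rng_seed)), class = "scene_spec")
}

#' Script a crossing event
#'
#' During a crossing, two flies walk straight paths that pass within
#' `min_dist` of each other at frame `frame`, their paths meeting at
#' `angle_deg`. A shallow angle gives the near-parallel pass that a tracker
#' should survive without swapping identities.
#'
#' @param frame Frame index (1-based) of closest approach.
#' @param flies Integer pair: which two flies cross.
#' @param angle_deg Angle between the two straight paths, degrees.
#' @param min_dist Closest-approach distance, pixels.
#' @return A one-row tibble understood by [simulate_motion()].
#' @export
crossing_event <- function(frame, flies, angle_deg = 30, min_dist = 8) {
  stopifnot(length(flies) == 2, flies[1] != flies[2], frame >= 1)
  tibble::tibble(frame = as.integer(frame), fly_a = as.integer(flies[1]),
                 fly_b = as.integer(flies[2]), angle_deg = angle_deg,
                 min_dist = min_dist)
}

# run fn with a private RNG stream seeded by `seed`, restoring global state
with_scene_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate ground-truth fly motion
#'
#' Per-fly correlated random walk: the heading performs a wrapped Gaussian
#' walk and the position advances along the heading by a jittered step.
#' With probability `jump_prob` per frame a fly jumps 5-15 steps in a
#' uniformly random direction (re-orienting to it). Flies reflect off the
#' arena wall, and outside scripted crossings a soft repulsion keeps pairs at
#' least `min_separation` apart so that uncrossed runs stay merge-free.
#' Scripted crossings steer the pair onto straight paths of equal speed whose
#' closest approach (`min_dist`) occurs at the scripted frame.
#'
#' @param spec A [scene_spec()].
#' @param crossings `NULL`, or a tibble of [crossing_event()] rows.
#' @return A tibble with columns `frame`, `fly`, `x`, `y`, `heading`,
#'   `event` (`"walk"`, `"jump"` or `"crossing"`), one row per (frame, fly);
#'   deterministic given `spec$rng_seed`.
#' @export
simulate_motion <- function(spec, crossings = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_rng(spec$rng_seed, function() simulate_motion_impl(spec, crossings))
}

simulate_motion_impl <- function(spec, crossings) {
  n <- spec$n_flies
  nf <- spec$n_frames
  if (n == 0) {
    return(tibble::tibble(frame = integer(), fly = integer(), x = numeric(),
                          y = numeric(), heading = numeric(),
                          event = character()))
  }
  ctr <- spec$arena_center
  rmax <- spec$arena_radius - spec$body_axes[1] - 1
  step <- spec$walk_speed

  # initial placement: rejection-sample positions >= min_separation apart
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {
      r <- rmax * 0.9 * sqrt(runif(1))
      a <- runif(1, 0, 2 * pi)
      p <- ctr + r * c(cos(a), sin(a))
      if (i == 1 ||
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2))) >= spec$min_separation) {
        pos[i, ] <- p
        break
      }
    }
  }
  hd <- runif(n, 0, 2 * pi)

  # precompute scripted crossing paths; the straight pass lasts until the
  # pair is comfortably separated again, so the separation hand-off back to
  # the random walk (and its repulsion) is smooth
  steer_len <- 25L
  # the straight pass begins at full min_separation (pre_half frames before
  # closest approach) and ends once the pair is comfortably apart again, so
  # neither steering nor the hand-off back to the random walk ever brings
  # the pair close outside the scripted pass itself
  halves_for <- function(ev) {
    rel_speed <- 2 * step * sin(ev$angle_deg * pi / 360)
    c(pre = min(50L, max(10L, ceiling(spec$min_separation /
                                        max(rel_speed, 1e-6)))),
      post = min(40L, max(10L, ceiling(0.6 * spec$min_separation /
                                         max(rel_speed, 1e-6)))))
  }
  scripts <- vector("list", n)  # per fly: list of (frames, x, y, heading)
  if (!is.null(crossings) && nrow(crossings) > 0) {
    crossings <- crossings[order(crossings$frame), , drop = FALSE]
  }

  out_x <- matrix(NA_real_, nf, n); out_y <- matrix(NA_real_, nf, n)
  out_h <- matrix(NA_real_, nf, n)
  out_e <- matrix("walk", nf, n)

  cross_active <- matrix(FALSE, nf, n)  # frames where scripting owns the fly
  path <- vector("list", n)             # per-fly scripted positions by frame

  plan_crossing <- function(ev, pos_now, frame_now) {
    i <- ev$fly_a; j <- ev$fly_b
    k <- ev$frame
    halves <- halves_for(ev)
    s0 <- max(frame_now, k - halves["pre"] - steer_len)  # steer start
    s1 <- max(s0, k - halves["pre"])                     # straight-path start
    s2 <- min(nf, k + halves["post"])
    mid <- (pos_now[i, ] + pos_now[j, ]) / 2
    # the pass spans up to pre_half * step pixels either side of the meeting
    # point, so clamp the meeting point near the arena centre
    reach <- max(halves) * step + 2 * spec$body_axes[1]
    max_mid <- max(0, rmax - reach)
    if (sqrt(sum((mid - ctr)^2)) > max_mid) {
      d <- mid - ctr
      mid <- ctr + if (max_mid > 0) d / sqrt(sum(d^2)) * max_mid else c(0, 0)
    }
    phi <- atan2(mid[2] - pos_now[i, 2], mid[1] - pos_now[i, 1])
    alpha <- ev$angle_deg * pi / 180
    vi <- step * c(cos(phi - alpha / 2), sin(phi - alpha / 2))
    vj <- step * c(cos(phi + alpha / 2), sin(phi + alpha / 2))
    dv <- vi - vj
    nrm <- c(-dv[2], dv[1]); nrm <- nrm / sqrt(sum(nrm^2))
    # offset perpendicular to the relative velocity makes the closest
    # approach exactly min_dist at frame k; the offset side is whichever
    # gives the shorter total steering
    start_of <- function(pk, v) pk + (s1 - k) * v
    cost_side <- function(s) {
      sqrt(sum((pos_now[i, ] - start_of(mid + s * nrm * ev$min_dist / 2,
                                        vi))^2)) +
        sqrt(sum((pos_now[j, ] - start_of(mid - s * nrm * ev$min_dist / 2,
                                          vj))^2))
    }
    s_opt <- if (cost_side(1) <= cost_side(-1)) 1 else -1
    pi_k <- mid + s_opt * nrm * ev$min_dist / 2   # fly i at closest approach
    pj_k <- mid - s_opt * nrm * ev$min_dist / 2
    mk <- function(pk, v) {
      fr <- s1:s2
      px <- pk[1] + (fr - k) * v[1]
      py <- pk[2] + (fr - k) * v[2]
      list(frames = fr, x = px, y = py, heading = atan2(v[2], v[1]),
           steer_from = s0)
    }
    list(i = i, j = j, pi = mk(pi_k, vi), pj = mk(pj_k, vj))
  }

  planned <- list()
  for (t in seq_len(nf)) {
    # activate scripts whose steer phase begins
    if (!is.null(crossings)) {
      for (r in seq_len(nrow(crossings))) {
        ev <- crossings[r, ]
        s0 <- max(1L, ev$frame - halves_for(ev)["pre"] - steer_len)
        if (t == s0) {
          pl <- plan_crossing(ev, pos, t)
          for (side in c("pi", "pj")) {
            fi <- if (side == "pi") pl$i else pl$j
            sc <- pl[[side]]
            path[[fi]] <- sc
            cross_active[sc$steer_from:max(sc$frames), fi] <- TRUE
            # steering interpolation anchors
            path[[fi]]$anchor <- pos[fi, ]
            path[[fi]]$anchor_frame <- t
          }
        }
      }
    }

    for (i in seq_len(n)) {
      sc <- path[[i]]
      if (!is.null(sc) && cross_active[t, i]) {
        f0 <- sc$frames[1]
        if (t < f0) {  # steer: linear interpolation to path start
          w <- (t - sc$anchor_frame) / (f0 - sc$anchor_frame)
          tgt <- c(sc$x[1], sc$y[1])
          newp <- (1 - w) * sc$anchor + w * tgt
          hd[i] <- atan2(newp[2] - pos[i, 2], newp[1] - pos[i, 1])
          pos[i, ] <- newp
        } else {
          idx <- t - f0 + 1L
          pos[i, ] <- c(sc$x[idx], sc$y[idx])
          hd[i] <- sc$heading
          out_e[t, i] <- "crossing"
        }
        if (!is.null(sc) && t == max(sc$frames)) path[i] <- list(NULL)
      } else {
        if (runif(1) < spec$jump_prob) {
          ang <- runif(1, 0, 2 * pi)
          len <- runif(1, spec$jump_range[1], spec$jump_range[2]) * step
          pos[i, ] <- pos[i, ] + len * c(cos(ang), sin(ang))
          hd[i] <- ang
          out_e[t, i] <- "jump"
        } else {
          hd[i] <- (hd[i] + rnorm(1, 0, spec$turn_sd)) %% (2 * pi)
          s <- step * runif(1, 0.5, 1.5)
          pos[i, ] <- pos[i, ] + s * c(cos(hd[i]), sin(hd[i]))
        }
      }
      # reflective arena boundary
      d <- pos[i, ] - ctr
      r <- sqrt(sum(d^2))
      if (r > rmax) {
        u <- d / r
        pos[i, ] <- ctr + u * (2 * rmax - r)
        # reflect heading about the tangent
        hv <- c(cos(hd[i]), sin(hd[i]))
        hv <- hv - 2 * sum(hv * u) * u
        hd[i] <- atan2(hv[2], hv[1]) %% (2 * pi)
      }
    }

    # soft repulsion between unscripted pairs; a free fly near a scripted
    # one takes the whole push (the scripted path must stay undisturbed,
    # so the free fly has to yield, fast enough to outrun the pass)
    if (n > 1) {
      for (pass in 1:5) {
        moved <- FALSE
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          if (cross_active[t, i] && cross_active[t, j]) next
          d <- pos[j, ] - pos[i, ]
          r <- sqrt(sum(d^2))
          if (r < spec$min_separation) {
            u <- if (r > 1e-9) d / r else c(cos(runif(1, 0, 2 * pi)),
                                            sin(runif(1, 0, 2 * pi)))
            deficit <- spec$min_separation - r + 1e-6
            if (cross_active[t, i] || cross_active[t, j]) {
              push <- min(deficit, 1.5 * step)
              if (!cross_active[t, i]) pos[i, ] <- pos[i, ] - u * push
              if (!cross_active[t, j]) pos[j, ] <- pos[j, ] + u * push
            } else {
              # cap at one walk step: separation is gradual, not a teleport
              push <- min(deficit / 2, step)
              pos[i, ] <- pos[i, ] - u * push
              pos[j, ] <- pos[j, ] + u * push
            }
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      # repulsion may push a fly out; clamp back inside
      for (i in seq_len(n)) {
        d <- pos[i, ] - ctr; r <- sqrt(sum(d^2))
        if (r > rmax) pos[i, ] <- ctr + d / r * rmax
      }
    }

    out_x[t, ] <- pos[, 1]; out_y[t, ] <- pos[, 2]; out_h[t, ] <- hd
  }

  tibble::tibble(
    frame = rep(seq_len(nf), times = n),
    fly = rep(seq_len(n), each = nf),
    x = as.vector(out_x), y = as.vector(out_y),
    heading = as.vector(out_h) %% (2 * pi),
    event = as.vector(out_e)
  ) |> dplyr::arrange(.data$frame, .data$fly)
}

# filled-ellipse mask evaluated over a bbox; returns cbind(col_index,
# row_index) of pixels (1-based matrix indices) inside the ellipse
ellipse_pixels <- function(dim_hw, center, semi_axes, angle) {
  A <- semi_axes[1]; B <- semi_axes[2]
  x0 <- center[1]; y0 <- center[2]
  xr <- max(0, floor(x0 - A - 1)):min(dim_hw[2] - 1, ceiling(x0 + A + 1))
  yr <- max(0, floor(y0 - A - 1)):min(dim_hw[1] - 1, ceiling(y0 + A + 1))
  if (length(xr) == 0 || length(yr) == 0) return(cbind(integer(), integer()))
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - x0; dy <- g$y - y0
  ca <- cos(angle); sa <- sin(angle)
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  keep <- (u / A)^2 + (v / B)^2 <= 1
  cbind(g$x[keep] + 1L, g$y[keep] + 1L)  # (col, row) 1-based
}

#' Render one fly onto a canvas
#'
#' Draws the body as a filled ellipse at `body_level` oriented along
#' `heading`, and two wing ellipses at `wing_level` fanned about the
#' anti-heading axis, centred about 0.9 semi-major lengths behind the
#' centroid so the wings trail past the tail. Compositing is `min()` (darkest
#' wins), so overlapping flies merge into one dark region.
#'
#' @param canvas Numeric matrix (a frame).
#' @param center `c(x, y)` body centre, 0-based pixels; must lie on canvas.
#' @param heading Heading angle, radians (centroid toward head).
#' @param spec A [scene_spec()] supplying levels and body axes.
#' @return The modified canvas.
#' @export
render_fly <- function(canvas, center, heading, spec) {
  d <- dim(canvas)
  if (center[1] < 0 || center[1] > d[2] - 1 ||
      center[2] < 0 || center[2] > d[1] - 1)
    stop("fly center lies outside the canvas")
  A <- spec$body_axes[1]; B <- spec$body_axes[2]
  u <- c(cos(heading), sin(heading))
  # wings first, body on top (min compositing keeps the body darkest)
  for (w in c(-1, 1)) {
    wang <- heading + pi + w * 25 * pi / 180
    wc <- center - u * 0.9 * A + 0.25 * A * c(cos(wang), sin(wang))
    px <- ellipse_pixels(d, wc, c(0.7 * A, 0.22 * A), wang)
    if (nrow(px) > 0) {
      idx <- cbind(px[, 2], px[, 1])
      canvas[idx] <- pmin(canvas[idx], spec$wing_level)
    }
  }
  px <- ellipse_pixels(d, center, c(A, B), heading)
  if (nrow(px) > 0) {
    idx <- cbind(px[, 2], px[, 1])
    canvas[idx] <- pmin(canvas[idx], spec$body_level)
  }
  canvas
}

#' Fly-free arena background plate
#'
#' @param spec A [scene_spec()].
#' @return Numeric matrix: `background_level` inside the arena disc, a darker
#'   surround (120) outside.
#' @export
arena_plate <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  r2 <- (xs - spec$arena_center[1])^2 + (ys - spec$arena_center[2])^2
  plate <- matrix(120, h, w)
  plate[r2 <= spec$arena_radius^2] <- spec$background_level
  plate
}

#' Render a ground-truth trajectory table into a frame stack
#'
#' Each frame is the arena plate plus `illumination_drift * (frame - 1)`,
#' with every fly rendered at its ground-truth pose, Gaussian pixel noise
#' added, and the result clipped to \[0, 255\] and quantized to whole gray
#' levels (as an 8-bit camera would).
#'
#' @param spec A [scene_spec()].
#' @param truth Tibble from [simulate_motion()] (consistent with `spec`).
#' @return A [frame_stack()].
#' @export
render_video <- function(spec, truth) {
  stopifnot(inherits(spec, "scene_spec"))
  n_frames <- spec$n_frames
  if (nrow(truth) > 0 && max(truth$frame) > n_frames)
    stop("truth has more frames than spec$n_frames")
  plate <- arena_plate(spec)
  with_scene_rng(spec$rng_seed + 1L, function() {
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      f <- plate + spec$illumination_drift * (t - 1)
      rows <- truth[truth$frame == t, , drop = FALSE]
      if (nrow(rows) > 0) {
        for (r in seq_len(nrow(rows)))
          f <- render_fly(f, c(rows$x[r], rows$y[r]), rows$heading[r], spec)
      }
      if (spec$noise_sd > 0)
        f <- f + matrix(rnorm(length(f), 0, spec$noise_sd), nrow(f))
      frames[[t]] <- round(clip255(f))
    }
    frame_stack(frames, fps = spec$fps)
  })
}

#' Convenience: simulate and render a synthetic arena video
#'
#' @inheritParams simulate_motion
#' @return A list with elements `stack` (a [frame_stack()]), `truth` (the
#'   ground-truth tibble) and `spec`.
#' @export
#' @examples
#' sv <- synth_video(scene_spec(n_flies = 2, n_frames = 5, image_size = c(120, 120),
#'                              arena_radius = 50, arena_center = c(59.5, 59.5)))
#' sv$stack
synth_video <- function(spec, crossings = NULL) {
  truth <- simulate_motion(spec, crossings)
  list(stack = render_video(spec, truth), truth = truth, spec = spec)
}
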