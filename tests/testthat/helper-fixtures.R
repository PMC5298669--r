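# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# a background_plate for a known arena image, bypassing mode extraction
plate_of <- function(img) {
  structure(list(image = img, mean_intensity = mean(img), n_samples = 1L),
            class = "background_plate")
}

# render one fly on the default arena and quantize like an 8-bit camera
single_fly_frame <- function(center, heading, spec = scene_spec(),
                             noise_sd = spec$noise_sd) {
  f <- render_fly(arena_plate(spec), center, heading, spec)
  if (noise_sd > 0) f <- f + matrix(rnorm(length(f), 0, noise_sd), nrow(f))
  round(pmin(pmax(f, 0), 255))
}

# all permutations of 1..n (for the brute-force assignment oracle)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exhaustive minimum assignment cost of a square matrix
brute_force_min_cost <- function(m) {
  p <- perms(nrow(m))
  costs <- apply(p, 1, function(pr) sum(m[cbind(seq_len(nrow(m)), pr)]))
  min(costs)
}

# independent greedy trace: sort all entries, sweep in (value, row, col)
# order, taking each pair whose row and column are still free
greedy_trace <- function(m) {
  ord <- order(as.vector(m),
               as.vector(row(m)),
               as.vector(col(m)))
  used_r <- rep(FALSE, nrow(m)); used_c <- rep(FALSE, ncol(m))
  total <- 0; pairs <- NULL
  for (k in ord) {
    r <- row(m)[k]; c <- col(m)[k]
    if (used_r[r] || used_c[c]) next
    used_r[r] <- TRUE; used_c[c] <- TRUE
    total <- total + m[r, c]
    pairs <- rbind(pairs, c(r, c))
  }
  list(total = total, pairs = pairs[order(pairs[, 1]), , drop = FALSE])
}

# random 8-connected-ish pixel blob around a centre (may be disconnected;
# fine for moment/centroid oracles, which are set-based)
random_blob <- function(n_px = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cx <- runif(1, 20, 200); cy <- runif(1, 20, 200)
  ang <- runif(1, 0, pi)
  l <- abs(rnorm(n_px, 0, 6)); w <- rnorm(n_px, 0, 2)
  px <- unique(cbind(x = round(cx + l * cos(ang) + w * -sin(ang)),
                     y = round(cy + l * sin(ang) + w * cos(ang))))
  list(pixels = px, values = rep(1, nrow(px)), area = nrow(px),
       centroid = c(mean(px[, 1]), mean(px[, 2])),
       bbox = c(x_min = min(px[, 1]), y_min = min(px[, 2]),
                width = diff(range(px[, 1])) + 1L,
                height = diff(range(px[, 2])) + 1L))
}

# eigendecomposition oracle for the ellipse fit
eigen_ellipse <- function(blob) {
  x <- blob$pixels[, 1]; y <- blob$pixels[, 2]
  C <- matrix(c(mean((x - mean(x))^2) + 1 / 12,
                mean((x - mean(x)) * (y - mean(y))),
                mean((x - mean(x)) * (y - mean(y))),
                mean((y - mean(y))^2) + 1 / 12), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  th <- atan2(v[2], v[1])
  if (th <= -pi / 2) th <- th + pi
  if (th > pi / 2) th <- th - pi
  list(a = 4 * sqrt(e$values[1]), b = 4 * sqrt(e$values[2]), theta = th)
}

# smallest absolute difference between two angles, radians
ang_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# anti-parallel near-miss: two flies approach head-on at `v` px/frame,
# stop `gap` apart, and retreat without turning; returns the tracker ids
# that end nearest fly 1 and fly 2
run_antiparallel <- function(use_gate, v = 10, gap = 10) {
  mk <- function(x1, x2) tibble::tibble(
    x = c(x1, x2), y = c(100, 100),
    heading_dx = c(1, -1), heading_dy = c(0, 0), heading_valid = TRUE)
  xs1 <- seq(100 - 20 * v, 100, by = v)
  xs2 <- seq(100 + gap + 20 * v, 100 + gap, by = -v)
  x1 <- c(xs1, seq(100 - v, 100 - 8 * v, by = -v))
  x2 <- c(xs2, seq(100 + gap + v, 100 + gap + 8 * v, by = v))
  cfg <- track_config(use_heading_gate = use_gate)
  trackers <- list(); next_id <- 1L
  for (t in seq_along(x1)) {
    st <- track_step(trackers, mk(x1[t], x2[t]), cfg, next_id)
    trackers <- st$trackers; next_id <- st$next_id
  }
  ids <- vapply(trackers, function(tr) tr$id, integer(1))
  pos <- vapply(trackers, function(tr) tr$state[1], numeric(1))
  c(fly1 = ids[which.min(abs(pos - tail(x1, 1)))],
    fly2 = ids[which.min(abs(pos - tail(x2, 1)))])
}

# manually-posed tracker (known velocity and heading) for step fixtures
posed_tracker <- function(id, pos, vel = c(0, 0), heading = NULL,
                          cfg = track_config()) {
  tr <- tracker_init(id, pos, heading, cfg)
  tr$state[3:4] <- vel
  tr
}

# the two-fly near-contact frame used by the splitting tests: four isolated
# flies fix the expected area, one pair sits 14 px apart (slight overlap)
near_contact_frame <- function(pair_dx = 14, seed = 1) {
  spec <- scene_spec(n_flies = 0, n_frames = 1)
  f <- arena_plate(spec)
  sep <- rbind(c(60, 60, 0.3), c(180, 60, 1.8), c(60, 180, 2.6),
               c(180, 180, 4.0))
  for (i in 1:4) f <- render_fly(f, sep[i, 1:2], sep[i, 3], spec)
  c1 <- c(120 - pair_dx / 2, 120); c2 <- c(120 + pair_dx / 2, 120)
  f <- render_fly(f, c1, 0.3, spec)
  f <- render_fly(f, c2, pi - 0.3, spec)
  set.seed(seed)
  f <- round(pmin(pmax(f + matrix(rnorm(length(f), 0, 2), nrow(f)), 0), 255))
  list(frame = f, plate = plate_of(arena_plate(spec)),
       pair = rbind(c1, c2), spec = spec)
}
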