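test_that("centroid and second moments match brute force and closed forms", {
  px1 <- list(pixels = cbind(x = 5L, y = 7L), area = 1L)
  expect_equal(blob_centroid(px1), c(5, 7))
  expect_equal(second_moments(px1), c(uxx = 1 / 12, uyy = 1 / 12, uxy = 0))

  sq <- list(pixels = cbind(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L)))
  expect_equal(blob_centroid(sq), c(0.5, 0.5))

  # horizontal 3-pixel line: uxx = 2/3 + 1/12, uyy = 1/12, uxy = 0
  line <- list(pixels = cbind(x = 0:2, y = c(0L, 0L, 0L)))
  expect_equal(second_moments(line), c(uxx = 0.75, uyy = 1 / 12, uxy = 0))

  # 90-degree rotation swaps uxx/uyy and negates uxy
  set.seed(101)
  b <- random_blob(50)
  rot <- list(pixels = cbind(x = -b$pixels[, 2], y = b$pixels[, 1]))
  m <- second_moments(b); mr <- second_moments(rot)
  expect_equal(unname(mr["uxx"]), unname(m["uyy"]))
  expect_equal(unname(mr["uyy"]), unname(m["uxx"]))
  expect_equal(unname(mr["uxy"]), -unname(m["uxy"]))

  # brute force on random blobs
  for (s in 1:5) {
    rb <- random_blob(50, seed = s)
    x <- rb$pixels[, 1]; y <- rb$pixels[, 2]
    expect_equal(blob_centroid(rb), c(sum(x) / length(x), sum(y) / length(y)),
                 tolerance = 1e-12)
    expect_equal(unname(second_moments(rb)["uxy"]),
                 sum((x - mean(x)) * (y - mean(y))) / length(x),
                 tolerance = 1e-12)
  }

  expect_error(blob_centroid(list(pixels = NULL)), "empty")
  expect_error(second_moments(list(pixels = NULL)), "empty")
})

test_that("ellipse fit reproduces closed forms and the eigen oracle", {
  # 3-pixel line: a = 2*sqrt(3), b = 2*sqrt(2)*sqrt(1/6), theta = 0
  fit <- ellipse_fit(c(uxx = 0.75, uyy = 1 / 12, uxy = 0), c(1, 0))
  expect_equal(fit$major, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(fit$minor, 2 * sqrt(2) * sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(fit$minor, 1.1547, tolerance = 1e-4)
  expect_equal(fit$theta, 0)

  # circular degenerate case
  circ <- ellipse_fit(c(uxx = 0.5, uyy = 0.5, uxy = 0), c(0, 0))
  expect_equal(circ$major, circ$minor)
  expect_equal(circ$theta, 0)

  # vertical line: theta = pi/2 (never -pi/2)
  vert <- ellipse_fit(c(uxx = 1 / 12, uyy = 0.75, uxy = 0), c(0, 0))
  expect_equal(vert$theta, pi / 2)

  # 500 random blobs against an independent eigendecomposition
  set.seed(202)
  for (i in 1:500) {
    rb <- random_blob(sample(20:80, 1))
    fit <- ellipse_fit(second_moments(rb), blob_centroid(rb))
    or <- eigen_ellipse(rb)
    expect_equal(fit$major, or$a, tolerance = 1e-9)
    expect_equal(fit$minor, or$b, tolerance = 1e-9)
    # theta defined modulo pi; compare axis directions
    expect_lt(min(abs(fit$theta - or$theta),
                  abs(abs(fit$theta - or$theta) - pi)), 1e-9)
    expect_gte(fit$major, fit$minor)
  }
})

test_that("wing scoring finds the head end on rendered flies", {
  spec <- scene_spec()
  plate <- plate_of(arena_plate(spec))
  set.seed(7)
  n_ok <- 0; n <- 40
  for (i in seq_len(n)) {
    h <- runif(1, 0, 2 * pi)
    ctr <- c(runif(1, 60, 180), runif(1, 60, 180))
    f <- single_fly_frame(ctr, h, spec)
    resp <- blob_filter(subtract_background(f, plate), log_kernel(6))
    blob <- label_blobs(threshold_blobs(resp, 0.5), min_area = 25)[[1]]
    fit <- ellipse_fit(second_moments(blob), blob_centroid(blob))
    hd <- heading_direction(blob, fit, f)
    expect_true(hd$valid)
    # direction is parallel to the fitted major axis
    expect_equal(abs(sum(hd$direction * c(cos(fit$theta), sin(fit$theta)))),
                 1, tolerance = 1e-9)
    # the wing (tail) end scores higher than the head end
    expect_gt(hd$score_tail_end, hd$score_head_end)
    ang <- atan2(hd$direction[2], hd$direction[1])
    if (ang_diff(ang, h) < 15 * pi / 180) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("mirroring the image mirrors the heading exactly", {
  spec <- scene_spec(noise_sd = 0)
  plate_img <- arena_plate(spec)
  f <- render_fly(plate_img, c(120, 120), 0.5, spec)
  fm <- f[, rev(seq_len(ncol(f)))]

  get_heading <- function(frame) {
    resp <- blob_filter(subtract_background(frame, plate_of(plate_img)),
                        log_kernel(6))
    blob <- label_blobs(threshold_blobs(resp, 0.5), min_area = 25)[[1]]
    fit <- ellipse_fit(second_moments(blob), blob_centroid(blob))
    heading_direction(blob, fit, frame)
  }
  h1 <- get_heading(f); h2 <- get_heading(fm)
  expect_true(h1$valid && h2$valid)
  expect_equal(h2$direction, c(-h1$direction[1], h1$direction[2]),
               tolerance = 1e-9)
})

test_that("degenerate and wing-less blobs give no heading verdict", {
  spec <- scene_spec(noise_sd = 0)
  plate_img <- arena_plate(spec)

  # blob with no intermediate-intensity pixels anywhere: body only, no wings
  f <- plate_img
  px <- which((row(f) - 121)^2 + (col(f) - 121)^2 <= 36)
  f[px] <- spec$body_level
  resp <- blob_filter(subtract_background(f, plate_of(plate_img)),
                      log_kernel(6))
  blob <- label_blobs(threshold_blobs(resp, 0.5), min_area = 25)[[1]]
  fit <- ellipse_fit(second_moments(blob), blob_centroid(blob))
  hd <- heading_direction(blob, fit, f)
  expect_false(hd$valid)  # circular: axis undefined

  # symmetric side-wing extension: scores tie, verdict withheld
  f2 <- plate_img
  xs <- row(f2) - 1; ys <- col(f2) - 1
  f2[((ys - 120) / 8)^2 + ((xs - 120) / 3)^2 <= 1] <- spec$body_level
  f2[abs(ys - 120) <= 2 & abs(xs - 120) >= 4 & abs(xs - 120) <= 10 &
       f2 > spec$wing_level] <- spec$wing_level
  resp2 <- blob_filter(subtract_background(f2, plate_of(plate_img)),
                       log_kernel(6))
  blob2 <- label_blobs(threshold_blobs(resp2, 0.5), min_area = 25)[[1]]
  fit2 <- ellipse_fit(second_moments(blob2), blob_centroid(blob2))
  hd2 <- heading_direction(blob2, fit2, f2)
  expect_false(hd2$valid)
})

test_that("fit_posture returns a complete one-row record", {
  spec <- scene_spec()
  set.seed(9)
  f <- single_fly_frame(c(120, 120), 1.2, spec)
  resp <- blob_filter(subtract_background(f, plate_of(arena_plate(spec))),
                      log_kernel(6))
  blob <- label_blobs(threshold_blobs(resp, 0.5), min_area = 25)[[1]]
  p <- fit_posture(blob, f)
  expect_named(p, c("x", "y", "a", "b", "theta", "heading_dx", "heading_dy",
                    "heading_valid"))
  expect_equal(nrow(p), 1)
  expect_lt(sqrt((p$x - 120)^2 + (p$y - 120)^2), 2)
  expect_true(p$heading_valid)
})
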