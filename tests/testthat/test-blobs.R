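test_that("LoG kernel matches its closed form and symmetries", {
  k1 <- log_kernel(sigma = 1, half_width = 4)
  h <- attr(k1, "half_width")
  expect_equal(k1[h + 1, h + 1], -1 / pi, tolerance = 1e-12)

  # zero crossing at radius sigma*sqrt(2): (x, y) = (1, 1) for sigma = 1
  expect_equal(k1[h + 2, h + 2], 0, tolerance = 1e-15)

  # symmetric under x<->-x, y<->-y, x<->y
  k6 <- log_kernel(6)
  expect_equal(k6, k6[rev(seq_len(nrow(k6))), ], ignore_attr = TRUE)
  expect_equal(k6, k6[, rev(seq_len(ncol(k6)))], ignore_attr = TRUE)
  expect_equal(unclass(k6), t(unclass(k6)), ignore_attr = TRUE)

  # minimum at the origin; sign change confined to radius 6*sqrt(2)
  h6 <- attr(k6, "half_width")
  expect_equal(which.min(k6), (h6 * (2 * h6 + 1)) + h6 + 1)
  g <- seq(-h6, h6)
  r <- sqrt(outer(g^2, g^2, "+"))
  expect_true(all(k6[r < 6 * sqrt(2) - 1e-9] < 0))
  expect_true(all(k6[r > 6 * sqrt(2) + 1e-9] > 0))

  expect_error(log_kernel(-1), "positive")
})

test_that("blob filter rejects DC and peaks at body-sized dark discs", {
  k <- log_kernel(4)
  flat <- matrix(100, 60, 60)
  r0 <- blob_filter(flat, k)
  expect_lt(max(abs(r0 - r0[30, 30])), 1e-9)  # constant response

  # dark disc of radius sigma*sqrt(2) on a light field: max response at centre
  img <- matrix(200, 81, 81)
  xs <- matrix(rep(0:80, each = 81), 81); ys <- t(xs)
  img[(xs - 40)^2 + (ys - 40)^2 <= (4 * sqrt(2))^2] <- 40
  resp <- blob_filter(img, k)
  expect_equal(which.max(resp), 40 * 81 + 41)  # centre pixel (40, 40)

  # adding a constant shifts the response only by c * sum(kernel) — a pure
  # offset, tiny because the (truncated) kernel nearly integrates to zero
  dc <- blob_filter(img + 30, k) - blob_filter(img, k)
  expect_lt(diff(range(dc)), 1e-9)
  expect_equal(mean(dc), 30 * sum(k), tolerance = 1e-9)
  expect_lt(abs(sum(k)), 0.005)
})

test_that("soft thresholding keeps values above the cut and zeroes the rest", {
  m <- matrix(c(-2, 0.3, 1.5, 4), 2)
  out <- threshold_blobs(m, 1)
  expect_equal(out, matrix(c(0, 0, 1.5, 4), 2))
  expect_true(all(threshold_blobs(m, 10) == 0))
  # threshold at the minimum keeps all nonnegative values intact
  kept <- threshold_blobs(m, min(m))
  expect_equal(kept[m >= 0], m[m >= 0])
})

test_that("blob labelling measures 8-connected components", {
  img <- matrix(0, 40, 40)
  img[21:23, 11:13] <- 1  # 3x3 square at x in 10..12, y in 20..22
  blobs <- label_blobs(img)
  expect_length(blobs, 1)
  expect_equal(blobs[[1]]$area, 9)
  expect_equal(blobs[[1]]$centroid, c(11, 21))
  expect_equal(unname(blobs[[1]]$bbox), c(10, 20, 3, 3))

  # two squares separated by two zero columns are distinct blobs
  img[21:23, 16:18] <- 1
  expect_length(label_blobs(img), 2)

  # diagonal contact joins under 8-connectivity
  d <- matrix(0, 10, 10)
  d[2, 2] <- 1; d[3, 3] <- 1
  expect_length(label_blobs(d), 1)

  # min_area filter
  expect_length(label_blobs(img, min_area = 10), 0)
  expect_error(label_blobs(matrix(-1, 2, 2)), "nonnegative")
})

test_that("labelled centroids equal the brute-force pixel mean", {
  set.seed(33)
  img <- matrix(0, 120, 120)
  img[matrix(sample(120 * 120, 800), ncol = 1)] <- runif(800, 0.5, 2)
  blobs <- label_blobs(img)
  for (b in blobs) {
    expect_equal(b$centroid,
                 c(sum(b$pixels[, 1]) / b$area, sum(b$pixels[, 2]) / b$area),
                 tolerance = 1e-12)
    expect_equal(b$area, nrow(b$pixels))
  }
})

test_that("threshold escalation splits touching flies but not heavy overlap", {
  nc <- near_contact_frame(pair_dx = 14)
  resp <- blob_filter(subtract_background(nc$frame, nc$plate), log_kernel(6))
  blobs <- label_blobs(threshold_blobs(resp, 0.5), min_area = 25)
  expect_length(blobs, 5)  # the pair merged into one blob

  split <- split_merged(blobs, split_config(base_threshold = 0.5))
  expect_length(split, 6)
  cents <- t(vapply(split, function(b) b$centroid, numeric(2)))
  for (r in 1:2) {
    d <- sqrt(rowSums(sweep(cents, 2, nc$pair[r, ])^2))
    expect_lt(min(d), 3)
  }
  # blob count never decreases; untouched blobs pass through unchanged
  expect_gte(length(split), length(blobs))

  # equal areas (the four isolated flies): no splitting at all
  singles <- blobs[vapply(blobs, function(b) b$area, numeric(1)) < 200]
  expect_length(singles, 4)
  expect_identical(split_merged(singles, split_config(base_threshold = 0.5)),
                   singles)

  # >70% body overlap: one response peak, split fails, single blob kept
  ov <- near_contact_frame(pair_dx = 3, seed = 2)
  resp2 <- blob_filter(subtract_background(ov$frame, ov$plate), log_kernel(6))
  blobs2 <- label_blobs(threshold_blobs(resp2, 0.5), min_area = 25)
  split2 <- split_merged(blobs2, split_config(base_threshold = 0.5))
  expect_length(split2, 5)
})

test_that("a fixture frame of well-separated flies yields one blob per fly", {
  spec <- scene_spec(n_flies = 10, n_frames = 1, rng_seed = 6)
  sv <- synth_video(spec)
  plate <- plate_of(arena_plate(spec))
  d <- detect_frame(sv$stack$frames[[1]], plate)
  expect_equal(nrow(d), 10)
  truth <- sv$truth[sv$truth$frame == 1, ]
  dist <- dist_mat <- outer(seq_len(10), seq_len(10), function(i, j)
    sqrt((d$x[i] - truth$x[j])^2 + (d$y[i] - truth$y[j])^2))
  expect_true(all(apply(dist_mat, 2, min) < 3))
})
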