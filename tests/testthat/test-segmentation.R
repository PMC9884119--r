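# Per-slice preprocessing, 2D detection, z-linking and label painting.

test_that("unsharp mask is the identity on constant images and at weight 0", {
  const <- matrix(7, 32, 32)
  expect_equal(unsharp_mask(const, radius_px = 2, weight = 0.6), const)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(unsharp_mask(img, radius_px = 2, weight = 0), img)
  expect_error(unsharp_mask(img, radius_px = 2, weight = 1), "weight")
})

test_that("unsharp mask matches a brute-force Gaussian convolution oracle", {
  # impulse image: direct evaluation of (I - w G(I)) / (1 - w) at the centre
  img <- matrix(0, 41, 41)
  img[21, 21] <- 1
  radius <- 2; w <- 0.6
  out <- unsharp_mask(img, radius_px = radius, weight = w)
  # oracle: sampled normalized Gaussian kernel, same truncation as the blur
  ksize <- 2 * ceiling(3 * radius) + 1
  xs <- seq(-(ksize - 1) / 2, (ksize - 1) / 2)
  k <- exp(-outer(xs^2, xs^2, "+") / (2 * radius^2))
  k <- k / sum(k)
  g_centre <- k[(ksize + 1) / 2, (ksize + 1) / 2]
  expected <- (1 - w * g_centre) / (1 - w)
  expected <- min(max(expected, 0), 1)  # clipped to input range
  expect_equal(out[21, 21], expected, tolerance = 1e-8)
})

test_that("percentile normalization maps ramps and constants per contract", {
  ramp <- matrix(seq(0, 255, length.out = 64), 8, 8)
  out <- normalize_percentiles(ramp, 0, 100)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(out, (ramp - min(ramp)) / diff(range(ramp)))
  expect_equal(normalize_percentiles(matrix(5, 8, 8), 1, 99.9),
               array(0, dim = c(8, 8)))
  # values below p_low exactly 0, above p_high exactly 1
  x <- matrix(1:1000, 25, 40)
  out2 <- normalize_percentiles(x, 1, 99.9)
  q <- sort(as.vector(x))[c(ceiling(0.01 * 999) + 1, 999)]  # loose brackets
  expect_true(all(out2[x < stats::quantile(x, 0.01)] == 0))
  expect_true(all(out2[x > stats::quantile(x, 0.999)] == 1))
  expect_error(normalize_percentiles(matrix(numeric(0), 0, 0)), "empty")
})

test_that("detector finds nothing on blank slices and splits separated blobs", {
  p <- seg_params()
  zero <- matrix(0, 96, 96)
  expect_length(detect_nuclei_2d(zero, p, pixel_size_um = 0.4), 0)
  expect_error(detect_nuclei_2d(zero, p), "calibration")

  one <- blob_slice(cx = 48, cy = 40, sigma = 3.2)
  d1 <- detect_nuclei_2d(one, p, pixel_size_um = 0.4)
  expect_length(d1, 1)
  expect_lt(abs(d1[[1]]$cx_um - 47 * 0.4), 0.4)  # centre at index 48 -> 0-based 47
  expect_lt(abs(d1[[1]]$cy_um - 39 * 0.4), 0.4)

  two <- blob_slice(cx = 28, cy = 48, sigma = 3.2) +
    blob_slice(cx = 68, cy = 48, sigma = 3.2)
  d2 <- detect_nuclei_2d(two, p, pixel_size_um = 0.4)
  expect_length(d2, 2)
})

test_that("raising the detection threshold never increases detection count", {
  set.seed(42)
  noisy <- blob_slice(cx = 30, cy = 30, sigma = 3) +
    blob_slice(cx = 60, cy = 60, sigma = 3) +
    matrix(runif(96 * 96, 0, 0.05), 96, 96)
  p <- seg_params()
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(thr) {
    length(detect_nuclei_2d(noisy, seg_params(detect_threshold = thr),
                            pixel_size_um = 0.4))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("area filter bounds are exclusive", {
  # a square patch of exactly 5 um^2 (or 30) must be dropped
  p <- seg_params()  # pixel 0.4 -> px area 0.16; need careful pixel counts
  sq <- function(npx_side) {
    m <- matrix(0, 64, 64)
    m[20 + seq_len(npx_side), 20 + seq_len(npx_side)] <- 1
    m
  }
  # 25 px = 4 um^2 < 5: dropped; 49 px = 7.84: kept; 196 px = 31.36 > 30: dropped
  expect_length(detect_nuclei_2d(sq(5), p, pixel_size_um = 0.4), 0)
  expect_length(detect_nuclei_2d(sq(7), p, pixel_size_um = 0.4), 1)
  expect_length(detect_nuclei_2d(sq(14), p, pixel_size_um = 0.4), 0)
})

test_that("z-linker keeps duration-6 tracks and drops duration-5 tracks", {
  p <- seg_params()
  six <- lapply(0:5, function(s) list(make_det(s, 10, 10)))
  tr6 <- link_z(six, p)
  expect_length(tr6, 1)
  expect_equal(tr6[[1]]$duration, 6)
  five <- lapply(0:4, function(s) list(make_det(s, 10, 10)))
  expect_length(link_z(five, p), 0)
  expect_length(link_z(list(), p), 0)
})

test_that("distant detection columns are never cross-linked", {
  p <- seg_params()  # max link 3 um; columns 9 um apart
  cols <- lapply(0:7, function(s) list(make_det(s, 10, 10),
                                       make_det(s, 19, 10)))
  tr <- link_z(cols, p)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, `[[`, numeric(1), "duration") == 8))
  xs <- sort(vapply(tr, function(t) t$centroid_um[1], numeric(1)))
  expect_equal(xs, c(10, 19))
})

test_that("no detection belongs to two tracks and durations respect the minimum", {
  set.seed(9)
  p <- seg_params(min_track_len = 3, max_link_dist_um = 2)
  # random jittered columns
  dbs <- lapply(0:9, function(s) {
    lapply(1:4, function(k) {
      make_det(s, k * 10 + rnorm(1, 0, 0.3), 10 + rnorm(1, 0, 0.3))
    })
  })
  tr <- link_z(dbs, p)
  expect_true(all(vapply(tr, `[[`, numeric(1), "duration") >= 3))
  # each (slice, centroid) appears in exactly one track
  keys <- unlist(lapply(tr, function(t) {
    vapply(t$detections, function(d) {
      paste(d$slice_index, d$cx_um, d$cy_um)
    }, character(1))
  }))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("tracks_to_labels paints additive masks with contiguous labels", {
  expect_equal(max(tracks_to_labels(list(), c(5, 10, 10), 0.4, 2)$data), 0)
  # one track of 6 disks of 20 px each -> 120 voxels
  idx20 <- as.integer(outer(31:35, (30:33) * 40, "+"))  # 5x4 = 20 px in 40x40
  dets <- lapply(0:5, function(s) {
    d <- make_det(s, 12, 13, idx = idx20, npx = 20)
    d
  })
  tr <- list(structure(list(track_id = 1, detections = dets, duration = 6,
                            centroid_um = c(12, 13, 5)), class = "Nucleus3D"))
  lv <- tracks_to_labels(tr, c(8, 40, 40), 0.4, 2)
  expect_equal(sum(lv$data == 1), 120)
  expect_setequal(unique(as.vector(lv$data)), c(0L, 1L))
  expect_error(tracks_to_labels(
    list(structure(list(track_id = 1, duration = 1, centroid_um = c(0, 0, 0),
                        detections = list(make_det(9, 1, 1, idx = 5L))),
                   class = "Nucleus3D")),
    c(5, 10, 10), 0.4, 2), "bounds")
})

test_that("segment_stack finds nothing in noise and is deterministic", {
  noise_spec <- tiny_spec(n_epi = 0, n_pre = 0, n_te = 0, seed = 13)
  out <- render_stack(noise_spec)
  seg <- segment_stack(out$stack)
  expect_length(seg$tracks, 0)
  expect_equal(max(seg$labels$data), 0)

  emb <- render_stack(tiny_spec(seed = 17))
  s1 <- segment_stack(emb$stack)
  s2 <- segment_stack(emb$stack)
  expect_identical(s1$labels$data, s2$labels$data)
  expect_gt(length(s1$tracks), 0)
})

test_that("greedy linking equals exhaustive assignment on mutual-NN instances", {
  set.seed(2024)
  n_checked <- 0L
  for (rep in seq_len(300)) {
    n_checked <- n_checked + check_linker_instance()
  }
  expect_gte(n_checked, 80)
})
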