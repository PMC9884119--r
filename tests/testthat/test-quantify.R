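# Measurement, QC filtering, region restriction and table export.

make_label_stack <- function() {
  # 4-slice, 10x10 stack, 2 channels; label 1 = 10 voxels of value 5 in ch1
  lab <- array(0L, dim = c(4, 10, 10))
  lab[2, 3:7, 4] <- 1L
  lab[3, 3:7, 4] <- 1L
  ch1 <- array(0, dim = c(4, 10, 10))
  ch1[lab == 1] <- 5
  ch2 <- array(0, dim = c(4, 10, 10))
  ch2[2, , ] <- 2
  data <- array(0L, dim = c(4, 10, 10, 2))
  data[, , , 1] <- as.integer(ch1)
  data[, , , 2] <- as.integer(ch2)
  list(labels = label_volume(lab, 0.5, 2),
       stack = image_stack(data, 0.5, 2, c("dapi", "py705")))
}

test_that("measure_nuclei reports exact means, integrated densities and volume", {
  fx <- make_label_stack()
  tab <- measure_nuclei(fx$labels, fx$stack, embryo_id = "e1")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$voxel_count, 10L)
  expect_equal(tab$mean_dapi, 5)
  expect_equal(tab$intden_dapi, 50)
  expect_equal(tab$volume_um3, 10 * 0.5^2 * 2)
  # ch2 has value 2 only on slice 2; label occupies 5 voxels there
  expect_equal(tab$intden_py705, 10)
  expect_equal(tab$mean_py705, 1)
  # centroid: rows 3:7 -> 0-based 2:6 mean 4 * 0.5 um; col 4 -> 1.5; z 1.5 slices * 2
  expect_equal(tab$y_um, 4 * 0.5)
  expect_equal(tab$x_um, 3 * 0.5)
  expect_equal(tab$z_um, 1.5 * 2)
})

test_that("measure_nuclei on an empty label volume returns an empty table", {
  fx <- make_label_stack()
  fx$labels$data[] <- 0L
  tab <- measure_nuclei(fx$labels, fx$stack)
  expect_equal(nrow(tab), 0)
  expect_true(all(c("mean_dapi", "intden_py705", "in_region") %in% names(tab)))
  bad <- label_volume(array(0L, dim = c(2, 10, 10)), 0.5, 2)
  expect_error(measure_nuclei(bad, fx$stack), "shape")
})

test_that("intden equals mean times voxel count exactly for every record", {
  emb <- render_stack(tiny_spec(seed = 31))
  seg <- segment_stack(emb$stack)
  tab <- measure_nuclei(seg$labels, emb$stack)
  expect_gt(nrow(tab), 0)
  for (ch in emb$stack$channels) {
    # exact up to one rounding of the mean (sum/n need not be representable)
    expect_equal(tab[[paste0("intden_", ch)]],
                 tab[[paste0("mean_", ch)]] * tab$voxel_count,
                 tolerance = 1e-14)
  }
  # total integrated density cannot exceed the channel total
  expect_lte(sum(tab$intden_dapi), sum(emb$stack$data[, , , 1]))
})

test_that("measured integrated density matches ground truth without noise", {
  out <- render_stack(one_nucleus_spec(seed = 41, amp = 90))
  seg <- segment_stack(out$stack)
  tab <- measure_nuclei(seg$labels, out$stack)
  expect_equal(nrow(tab), 1)
  # the detection mask trims sub-threshold blob tails, so measured intden is
  # slightly below the rendered total but must stay close
  ratio <- tab$intden_py705 / out$truth$total_py705
  expect_gt(ratio, 0.7)
  expect_lte(ratio, 1.001)
})

test_that("qc_filter applies open intervals and is idempotent", {
  thr <- qc_thresholds()  # DAPI (2,10), volume (150,700)
  tab <- toy_table(rep(1000, 7))
  tab$dapi_mean_qc <- c(5, 1, 5, 2, 10, 5, 5)
  tab$volume_um3 <- c(300, 300, 800, 300, 300, 150, 700)
  kept <- qc_filter(tab, thr)
  # hand-determined survivor set: only row 1 (5, 300)
  expect_equal(kept$nucleus_id, 1L)
  expect_identical(qc_filter(kept, thr), kept)
  # boundary values (dapi 2 or 10, volume 150 or 700) are removed
  expect_false(any(kept$dapi_mean_qc %in% c(2, 10)))
  # subset property
  expect_true(all(kept$record_id %in% tab$record_id))
  # raw-scale option
  tab$mean_dapi <- c(5, 50, 5, 5, 5, 5, 5) * 25.5 / 25.5
  kept_raw <- qc_filter(tab, thr, dapi_scale = "raw")
  expect_true(all(kept_raw$mean_dapi > 2 & kept_raw$mean_dapi < 10))
})

test_that("three-record toy set keeps exactly one survivor", {
  tab <- toy_table(rep(1, 3))
  tab$dapi_mean_qc <- c(5, 1, 5)
  tab$volume_um3 <- c(300, 300, 800)
  expect_equal(nrow(qc_filter(tab, qc_thresholds())), 1)
})

test_that("apply_region flags centroid membership", {
  tab <- toy_table(rep(1, 3))
  tab$x_um <- c(1, 5, 9); tab$y_um <- c(1, 1, 1); tab$z_um <- c(0, 0, 0)
  roi <- array(TRUE, dim = c(2, 12, 26))
  expect_true(all(apply_region(tab, roi, 0.4, 2)$in_region))
  expect_false(any(apply_region(tab, !roi, 0.4, 2)$in_region))
  # half-space ROI: x >= 5 um -> voxel index >= 13
  half <- array(FALSE, dim = c(2, 12, 26))
  half[, , 13:26] <- TRUE
  expect_equal(apply_region(tab, half, 0.4, 2)$in_region,
               c(FALSE, TRUE, TRUE))
  expect_error(apply_region(tab, matrix(TRUE, 2, 2), 0.4, 2))
})

test_that("embryo tables round-trip losslessly through CSV", {
  emb <- render_stack(tiny_spec(seed = 37))
  seg <- segment_stack(emb$stack)
  tab <- measure_nuclei(seg$labels, emb$stack, embryo_id = "rt",
                        stage = "E3.5", genotype = "WT")
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(tab, path)
  back <- read_embryo_table(path)
  expect_identical(names(back), names(tab))
  for (nm in names(tab)) expect_identical(back[[nm]], tab[[nm]], info = nm)
  # empty table -> header-only file
  export_table(tab[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_embryo_table(path)), 0)
  # n-record table -> n + 1 lines
  export_table(tab[seq_len(3), ], path)
  expect_equal(length(readLines(path)), 4)
})
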