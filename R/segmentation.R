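#' Segmentation parameters
#'
#' Defaults encode the protocol constants of the pipeline: unsharp mask
#' radius 15 px / weight 0.6 on the DNA channel,
#' percentile normalization to the 1.0-99.9 window, detection threshold 0.2
#' on the normalized scale, overlap suppression at 0.2 IoU, per-slice area
#' filter strictly inside (5, 30) um^2, and a minimum track duration of 6
#' slices (i.e. strictly more than 5). Units of the area filter and the
#' linking distance are configuration choices; defaults interpret them as
#' calibrated micrometre units.
#'
#' @param unsharp_radius_px Gaussian sigma of the unsharp mask, pixels.
#' @param unsharp_weight Unsharp mask weight in `[0, 1)`.
#' @param percentile_low,percentile_high Percentiles mapped to 0 and 1.
#' @param detect_threshold Detection threshold on the normalized image.
#' @param overlap_suppression IoU above which overlapping candidates are
#'   suppressed (keep the one with larger mean intensity).
#' @param area_min_um2,area_max_um2 Exclusive per-slice area bounds, um^2.
#' @param max_link_dist_um Maximum xy centroid distance for a z-link.
#' @param min_track_len Minimum number of consecutive slices for a retained
#'   3D object.
#' @param max_gap Maximum number of skipped slices inside a track (default 0:
#'   tracks must be slice-consecutive).
#' @param split_method How touching nuclei inside one thresholded component
#'   are separated: `"intensity"` (default) runs the watershed on the
#'   smoothed normalized intensity, exploiting the deep brightness valleys
#'   between adjacent nuclei; `"distance"` runs it on the distance
#'   transform, which only sees mask shape and under-splits deeply
#'   overlapping masks.
#' @param watershed_tolerance Minimum peak-to-saddle height for two
#'   watershed objects to stay separate, in units of the chosen elevation
#'   (normalized intensity for `"intensity"`, pixels for `"distance"`).
#' @param watershed_smooth_px Gaussian sigma (px) applied to the normalized
#'   slice before the intensity watershed, suppressing noise maxima.
#' @return List of class `SegmentationParams`.
#' @export
seg_params <- function(unsharp_radius_px = 15, unsharp_weight = 0.6,
                       percentile_low = 1.0, percentile_high = 99.9,
                       detect_threshold = 0.2, overlap_suppression = 0.2,
                       area_min_um2 = 5, area_max_um2 = 30,
                       max_link_dist_um = 3, min_track_len = 6,
                       max_gap = 0, split_method = "intensity",
                       watershed_tolerance = if (split_method == "intensity") 0.1 else 1,
                       watershed_smooth_px = 1.5) {
  stopifnot(percentile_low >= 0, percentile_high <= 100,
            percentile_low < percentile_high)
  stopifnot(detect_threshold >= 0, detect_threshold <= 1,
            overlap_suppression >= 0, overlap_suppression <= 1)
  stopifnot(area_min_um2 < area_max_um2, min_track_len >= 1, max_gap >= 0)
  split_method <- match.arg(split_method, c("intensity", "distance"))
  structure(
    list(unsharp_radius_px = unsharp_radius_px,
         unsharp_weight = unsharp_weight,
         percentile_low = percentile_low, percentile_high = percentile_high,
         detect_threshold = detect_threshold,
         overlap_suppression = overlap_suppression,
         area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
         max_link_dist_um = max_link_dist_um, min_track_len = min_track_len,
         max_gap = max_gap, split_method = split_method,
         watershed_tolerance = watershed_tolerance,
         watershed_smooth_px = watershed_smooth_px),
    class = "SegmentationParams"
  )
}

#' Unsharp mask (normalized convention)
#'
#' `out = (I - w * G_sigma(I)) / (1 - w)` with `G_sigma` a Gaussian blur of
#' sigma `radius_px`, clipped back to the input's value range. A constant
#' image is returned unchanged and `weight = 0` is the identity.
#'
#' @param img 2D numeric matrix.
#' @param radius_px Gaussian sigma in pixels (> 0).
#' @param weight Mask weight in `[0, 1)`.
#' @return Sharpened matrix, same dimensions.
#' @export
unsharp_mask <- function(img, radius_px, weight) {
  stopifnot(is.matrix(img), radius_px > 0)
  if (weight < 0 || weight >= 1) {
    stop("unsharp weight must be in [0, 1)", call. = FALSE)
  }
  if (weight == 0) return(img)
  g <- EBImage::gblur(img, sigma = radius_px, boundary = "replicate")
  out <- (img - weight * g) / (1 - weight)
  clip(out, min(img), max(img))
}

#' Percentile normalization to [0, 1]
#'
#' Linearly rescales so the `p_low` percentile maps to 0 and the `p_high`
#' percentile to 1, then clips to `[0, 1]`. A constant image maps to all
#' zeros.
#'
#' @param img 2D numeric matrix (nonempty).
#' @param p_low,p_high Percentiles in `[0, 100]`, `p_low < p_high`.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_percentiles <- function(img, p_low = 1.0, p_high = 99.9) {
  if (length(img) == 0) stop("empty image", call. = FALSE)
  stopifnot(p_low < p_high)
  q <- stats::quantile(img, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim = dim(img)))
  clip((img - q[1]) / (q[2] - q[1]), 0, 1)
}

#' Detect nucleus candidates in one normalized slice
#'
#' Thresholds at `detect_threshold`, fills holes, splits touching nuclei by
#' a watershed (on smoothed intensity by default, on the distance transform
#' optionally; see [seg_params()]), suppresses overlapping candidates above
#' the IoU limit (keeping the larger mean intensity), and applies the
#' exclusive per-slice area filter.
#'
#' @param norm_slice 2D matrix in `[0, 1]`.
#' @param params [seg_params()].
#' @param pixel_size_um xy calibration (required).
#' @param raw_slice Optional raw DNA slice for `mean_dna` (8-bit units);
#'   defaults to the normalized slice.
#' @param slice_index 0-based slice index recorded on each detection.
#' @return List of detections; each has `slice_index`, `idx` (pixel indices
#'   into the slice matrix), `npx`, `area_um2`, `cx_um`, `cy_um`, `mean_dna`.
#' @export
detect_nuclei_2d <- function(norm_slice, params = seg_params(),
                             pixel_size_um = NULL, raw_slice = NULL,
                             slice_index = 0L) {
  if (is.null(pixel_size_um)) {
    stop("missing calibration: pixel_size_um", call. = FALSE)
  }
  raw_slice <- raw_slice %||% norm_slice
  bw <- norm_slice > params$detect_threshold
  if (!any(bw)) return(list())
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  elev <- if (identical(params$split_method, "distance")) {
    EBImage::distmap(bw)
  } else {
    sm <- if (params$watershed_smooth_px > 0) {
      EBImage::gblur(norm_slice, sigma = params$watershed_smooth_px,
                     boundary = "replicate")
    } else {
      norm_slice
    }
    EBImage::Image(sm * (EBImage::imageData(bw) > 0))
  }
  lab <- EBImage::watershed(elev, tolerance = params$watershed_tolerance,
                            ext = 1)
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  px2 <- pixel_size_um^2
  nr <- nrow(norm_slice)
  dets <- list()
  idx_by_lab <- split(seq_along(lab)[lab > 0], lab[lab > 0])
  for (ids in idx_by_lab) {
    npx <- length(ids)
    area <- npx * px2
    if (!(area > params$area_min_um2 && area < params$area_max_um2)) next
    rows <- ((ids - 1) %% nr) + 1
    cols <- ((ids - 1) %/% nr) + 1
    dets[[length(dets) + 1L]] <- list(
      slice_index = as.integer(slice_index),
      idx = as.integer(ids), npx = npx, area_um2 = area,
      cx_um = mean(cols - 1) * pixel_size_um,
      cy_um = mean(rows - 1) * pixel_size_um,
      mean_dna = mean(raw_slice[ids])
    )
  }
  suppress_overlaps(dets, params$overlap_suppression)
}

#' Suppress overlapping 2D candidates by IoU
#'
#' Pairs of candidates with mask IoU above `iou_max` are reduced to the one
#' with the larger mean DNA intensity (ties: the earlier candidate). With
#' disjoint watershed labels this is a no-op; it matters when candidate sets
#' from other sources overlap.
#'
#' @param dets List of detections (as from [detect_nuclei_2d()]).
#' @param iou_max IoU threshold.
#' @return Filtered detection list.
#' @export
suppress_overlaps <- function(dets, iou_max) {
  n <- length(dets)
  if (n <= 1) return(dets)
  keep <- rep(TRUE, n)
  ord <- order(-vapply(dets, `[[`, numeric(1), "mean_dna"), seq_len(n))
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq((a + 1), n)) {
      j <- ord[b]
      if (!keep[j]) next
      inter <- length(intersect(dets[[i]]$idx, dets[[j]]$idx))
      if (inter == 0) next
      iou <- inter / (dets[[i]]$npx + dets[[j]]$npx - inter)
      if (iou > iou_max) keep[j] <- FALSE
    }
  }
  dets[keep]
}

#' Link 2D detections through the z-stack into 3D objects
#'
#' Greedy nearest-neighbour linking between consecutive slices on xy
#' centroid distance: candidate links sorted by (distance, detection index),
#' accepted while both ends are free and the distance is at most
#' `max_link_dist_um`. Each detection joins at most one track; tracks must
#' be slice-consecutive up to `max_gap` skipped slices (default 0). Tracks
#' shorter than `min_track_len` slices are discarded, implementing the
#' "duration strictly greater than 5" retention rule at the default.
#'
#' @param detections_by_slice List (ordered by slice) of detection lists.
#' @param params [seg_params()].
#' @return List of `Nucleus3D` objects: `track_id`, `detections` (ordered),
#'   `duration`, `centroid_um` (mean detection centroid, z from slice index).
#' @param z_step_um Axial calibration used for track centroids.
#' @export
link_z <- function(detections_by_slice, params = seg_params(), z_step_um = 2) {
  nz <- length(detections_by_slice)
  tracks <- list()      # each: list(det_idx = list of (slice, j), last_slice)
  open_idx <- integer(0)  # indices into tracks that may still be extended
  for (s in seq_len(nz)) {
    dets <- detections_by_slice[[s]]
    nd <- length(dets)
    # drop tracks whose last slice is too far back to extend
    if (length(open_idx) > 0) {
      last <- vapply(tracks[open_idx], `[[`, numeric(1), "last_slice")
      open_idx <- open_idx[s - last <= params$max_gap + 1]
    }
    if (nd > 0 && length(open_idx) > 0) {
      ends <- t(vapply(tracks[open_idx], function(tr) tr$end_xy,
                       numeric(2)))
      cand <- expand.grid(ti = seq_along(open_idx), dj = seq_len(nd))
      dx <- ends[cand$ti, 1] - vapply(dets, `[[`, numeric(1), "cx_um")[cand$dj]
      dy <- ends[cand$ti, 2] - vapply(dets, `[[`, numeric(1), "cy_um")[cand$dj]
      cand$dist <- sqrt(dx^2 + dy^2)
      cand <- cand[cand$dist <= params$max_link_dist_um, , drop = FALSE]
      cand <- cand[order(cand$dist, cand$dj, cand$ti), , drop = FALSE]
      used_t <- logical(length(open_idx))
      used_d <- logical(nd)
      for (r in seq_len(nrow(cand))) {
        ti <- cand$ti[r]; dj <- cand$dj[r]
        if (used_t[ti] || used_d[dj]) next
        used_t[ti] <- TRUE; used_d[dj] <- TRUE
        k <- open_idx[ti]
        tracks[[k]]$dets <- c(tracks[[k]]$dets, list(dets[[dj]]))
        tracks[[k]]$last_slice <- s
        tracks[[k]]$end_xy <- c(dets[[dj]]$cx_um, dets[[dj]]$cy_um)
      }
      new_open <- open_idx[used_t]
      # unmatched detections start new tracks
      for (dj in which(!used_d)) {
        tracks[[length(tracks) + 1L]] <- list(
          dets = list(dets[[dj]]), last_slice = s,
          end_xy = c(dets[[dj]]$cx_um, dets[[dj]]$cy_um)
        )
        new_open <- c(new_open, length(tracks))
      }
      # tracks not extended this slice stay open (gap) if allowed
      stale <- open_idx[!used_t]
      open_idx <- sort(c(new_open, stale))
    } else if (nd > 0) {
      for (dj in seq_len(nd)) {
        tracks[[length(tracks) + 1L]] <- list(
          dets = list(dets[[dj]]), last_slice = s,
          end_xy = c(dets[[dj]]$cx_um, dets[[dj]]$cy_um)
        )
        open_idx <- c(open_idx, length(tracks))
      }
    }
  }
  kept <- Filter(function(tr) length(tr$dets) >= params$min_track_len, tracks)
  out <- vector("list", length(kept))
  for (k in seq_along(kept)) {
    dets <- kept[[k]]$dets
    cx <- mean(vapply(dets, `[[`, numeric(1), "cx_um"))
    cy <- mean(vapply(dets, `[[`, numeric(1), "cy_um"))
    cz <- mean(vapply(dets, `[[`, numeric(1), "slice_index")) * z_step_um
    out[[k]] <- structure(
      list(track_id = k, detections = dets,
           duration = length(dets), centroid_um = c(cx, cy, cz)),
      class = "Nucleus3D"
    )
  }
  out
}

#' Rasterize tracks into a 3D label volume
#'
#' Label `k` is the union of track `k`'s per-slice pixel masks. A voxel
#' claimed by two tracks is resolved to the track with the nearer 3D
#' centroid (deterministic).
#'
#' @param tracks List of `Nucleus3D` from [link_z()].
#' @param stack_shape `(n_z, n_y, n_x)`.
#' @param pixel_size_um,z_step_um Calibration.
#' @return A `LabelVolume` with contiguous labels `1..K`.
#' @export
tracks_to_labels <- function(tracks, stack_shape, pixel_size_um, z_step_um) {
  nz <- stack_shape[1]; ny <- stack_shape[2]; nx <- stack_shape[3]
  lab <- array(0L, dim = c(nz, ny, nx))
  npx_slice <- ny * nx
  for (k in seq_along(tracks)) {
    for (det in tracks[[k]]$detections) {
      z <- det$slice_index + 1L
      if (z < 1 || z > nz || any(det$idx < 1) || any(det$idx > npx_slice)) {
        stop("detection outside stack bounds", call. = FALSE)
      }
      plane <- lab[z, , ]
      dim(plane) <- c(ny, nx)
      conflict <- det$idx[plane[det$idx] > 0]
      free <- setdiff(det$idx, conflict)
      plane[free] <- k
      for (ci in conflict) {
        other <- plane[ci]
        r <- ((ci - 1) %% ny)
        cl <- ((ci - 1) %/% ny)
        v <- c(cl * pixel_size_um, r * pixel_size_um,
               det$slice_index * z_step_um)
        d_new <- sum((v - tracks[[k]]$centroid_um)^2)
        d_old <- sum((v - tracks[[other]]$centroid_um)^2)
        if (d_new < d_old) plane[ci] <- k
      }
      lab[z, , ] <- plane
    }
  }
  # relabel to contiguous 1..K in first-appearance order
  present <- sort(unique(lab[lab > 0]))
  if (length(present) > 0 && !identical(present, seq_along(present))) {
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    pos <- lab > 0
    lab[pos] <- remap[lab[pos]]
  }
  label_volume(lab, pixel_size_um, z_step_um)
}

#' Segment a full stack: detect per slice, link through z, rasterize
#'
#' Runs unsharp masking and percentile normalization on the DNA channel of
#' every slice, detects 2D candidates, links them into 3D objects, applies
#' the duration filter and paints the label volume. Counts at each stage are
#' returned for the run log.
#'
#' @param stack An `ImageStack`.
#' @param params [seg_params()].
#' @param dna_channel DNA channel name or index (default `"dapi"` if
#'   present, else channel 1).
#' @return List: `labels` (a `LabelVolume`), `tracks` (list of `Nucleus3D`),
#'   `log` (named counts: `detections_2d`, `tracks_all`, `tracks_retained`).
#' @export
segment_stack <- function(stack, params = seg_params(), dna_channel = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.null(dna_channel)) {
    dna_channel <- if ("dapi" %in% stack$channels) "dapi" else 1L
  }
  ci <- resolve_channel(stack, dna_channel)
  nz <- dim(stack$data)[1]
  det_by_slice <- vector("list", nz)
  n_det <- 0L
  for (z in seq_len(nz)) {
    raw <- get_slice(stack, z, ci)
    sharp <- unsharp_mask(raw, params$unsharp_radius_px, params$unsharp_weight)
    norm <- normalize_percentiles(sharp, params$percentile_low,
                                  params$percentile_high)
    det_by_slice[[z]] <- detect_nuclei_2d(
      norm, params, pixel_size_um = stack$pixel_size_um,
      raw_slice = raw, slice_index = z - 1L
    )
    n_det <- n_det + length(det_by_slice[[z]])
  }
  all_tracks <- link_z(det_by_slice,
                       seg_params_with(params, min_track_len = 1),
                       z_step_um = stack$z_step_um)
  tracks <- Filter(function(tr) tr$duration >= params$min_track_len,
                   all_tracks)
  tracks <- lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]; tr$track_id <- k; tr
  })
  labels <- tracks_to_labels(tracks, dim(stack$data)[1:3],
                             stack$pixel_size_um, stack$z_step_um)
  list(
    labels = labels, tracks = tracks,
    log = c(detections_2d = n_det, tracks_all = length(all_tracks),
            tracks_retained = length(tracks))
  )
}

seg_params_with <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  params
}
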