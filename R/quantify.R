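#' Quality-control thresholds for segmented nuclei
#'
#' Default windows: mean DAPI signal strictly inside
#' (2, 10) and volume strictly inside (150, 700). Both windows are open
#' intervals — boundary-equal records are removed. The DAPI window is
#' applied, by default, to the nucleus mean DAPI rescaled from the 8-bit
#' acquisition scale to 0-10 (`mean / 255 * 10`); the volume window to the
#' calibrated volume in um^3. Both scales are configurable in [qc_filter()].
#'
#' @param dapi_mean_low,dapi_mean_high Open-interval bounds for mean DAPI.
#' @param volume_low,volume_high Open-interval bounds for nucleus volume.
#' @return List of class `QCThresholds`.
#' @export
qc_thresholds <- function(dapi_mean_low = 2, dapi_mean_high = 10,
                          volume_low = 150, volume_high = 700) {
  stopifnot(dapi_mean_low < dapi_mean_high, volume_low < volume_high)
  structure(
    list(dapi_mean_low = dapi_mean_low, dapi_mean_high = dapi_mean_high,
         volume_low = volume_low, volume_high = volume_high),
    class = "QCThresholds"
  )
}

#' Measure every 3D nucleus of a label volume
#'
#' For each label, computes the unweighted voxel centroid (physical um,
#' z = slice index x z-step), voxel count, calibrated volume, and per
#' channel the mean intensity and integrated density (sum over all voxel
#' values in the 3D object). Also carries `dapi_mean_qc`, the mean DAPI on
#' the 0-10 QC scale, when a DAPI channel is present.
#'
#' @param labels A `LabelVolume`.
#' @param stack The matching `ImageStack` (same shape and calibration).
#' @param embryo_id,stage,genotype Metadata attached to every record.
#' @return Data frame (the embryo table) with one row per nucleus:
#'   `embryo_id`, `nucleus_id`, `x_um`, `y_um`, `z_um`, `voxel_count`,
#'   `volume_um3`, `mean_<ch>` / `intden_<ch>` per channel, `dapi_mean_qc`,
#'   `in_region`, `stage`, `genotype`, `record_id`.
#' @export
measure_nuclei <- function(labels, stack, embryo_id = "embryo",
                           stage = NA_character_, genotype = NA_character_) {
  stopifnot(inherits(labels, "LabelVolume"), inherits(stack, "ImageStack"))
  if (!identical(dim(labels$data), dim(stack$data)[1:3])) {
    stop("label volume and stack shapes differ", call. = FALSE)
  }
  lab <- labels$data
  d <- dim(lab)
  idx <- which(lab > 0)
  chans <- stack$channels
  empty <- make_embryo_table_skeleton(chans)
  if (length(idx) == 0) return(empty)
  labv <- lab[idx]
  ord <- order(labv, idx)
  idx <- idx[ord]; labv <- labv[ord]
  # array index decomposition for (z, y, x) dims
  z0 <- (idx - 1) %% d[1]
  y0 <- ((idx - 1) %/% d[1]) %% d[2]
  x0 <- (idx - 1) %/% (d[1] * d[2])
  f <- factor(labv)
  nvox <- as.integer(tabulate(f))
  px <- labels$pixel_size_um; dz <- labels$z_step_um
  tab <- data.frame(
    embryo_id = embryo_id,
    nucleus_id = as.integer(levels(f)),
    x_um = as.numeric(rowsum(x0, f)) / nvox * px,
    y_um = as.numeric(rowsum(y0, f)) / nvox * px,
    z_um = as.numeric(rowsum(z0, f)) / nvox * dz,
    voxel_count = nvox,
    volume_um3 = nvox * px^2 * dz,
    stringsAsFactors = FALSE
  )
  slab_n <- d[1] * d[2] * d[3]
  for (ci in seq_along(chans)) {
    vals <- stack$data[idx + (ci - 1) * slab_n]
    sums <- as.numeric(rowsum(vals, f))
    tab[[paste0("intden_", chans[ci])]] <- sums
    tab[[paste0("mean_", chans[ci])]] <- sums / nvox
  }
  # fixed column order: means before integrated densities, per channel
  ord_cols <- c("embryo_id", "nucleus_id", "x_um", "y_um", "z_um",
                "voxel_count", "volume_um3",
                as.vector(rbind(paste0("mean_", chans),
                                paste0("intden_", chans))))
  tab <- tab[, ord_cols]
  if ("dapi" %in% chans) {
    tab$dapi_mean_qc <- tab$mean_dapi / (2^stack$bit_depth - 1) * 10
  } else {
    tab$dapi_mean_qc <- NA_real_
  }
  tab$in_region <- TRUE
  tab$stage <- stage
  tab$genotype <- genotype
  tab$record_id <- paste(tab$embryo_id, tab$nucleus_id, sep = ":")
  tab
}

make_embryo_table_skeleton <- function(chans) {
  tab <- data.frame(
    embryo_id = character(0), nucleus_id = integer(0),
    x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
    voxel_count = integer(0), volume_um3 = numeric(0),
    stringsAsFactors = FALSE
  )
  for (ch in chans) {
    tab[[paste0("mean_", ch)]] <- numeric(0)
    tab[[paste0("intden_", ch)]] <- numeric(0)
  }
  tab$dapi_mean_qc <- numeric(0)
  tab$in_region <- logical(0)
  tab$stage <- character(0)
  tab$genotype <- character(0)
  tab$record_id <- character(0)
  tab
}

#' Remove erroneously segmented nuclei by DAPI-signal and volume windows
#'
#' Keeps records whose DAPI mean and volume lie strictly inside the open
#' intervals of `thr`; everything else (over- and under-segmented objects,
#' debris) is dropped. Idempotent; output is always a subset of input.
#'
#' @param table Embryo table from [measure_nuclei()].
#' @param thr [qc_thresholds()].
#' @param dapi_scale `"norm10"` (default): apply the DAPI window to
#'   `dapi_mean_qc` (8-bit mean rescaled to 0-10); `"raw"`: apply it to
#'   `mean_dapi` in 8-bit units.
#' @param volume_units `"um3"` (default) or `"voxels"`.
#' @param quiet Suppress the removed-count message.
#' @return Filtered embryo table.
#' @export
qc_filter <- function(table, thr = qc_thresholds(),
                      dapi_scale = c("norm10", "raw"),
                      volume_units = c("um3", "voxels"),
                      quiet = TRUE) {
  dapi_scale <- match.arg(dapi_scale)
  volume_units <- match.arg(volume_units)
  dapi <- switch(dapi_scale, norm10 = table$dapi_mean_qc,
                 raw = table$mean_dapi)
  vol <- switch(volume_units, um3 = table$volume_um3,
                voxels = table$voxel_count)
  if (is.null(dapi) || is.null(vol)) {
    stop("table lacks DAPI mean and/or volume columns", call. = FALSE)
  }
  keep <- dapi > thr$dapi_mean_low & dapi < thr$dapi_mean_high &
    vol > thr$volume_low & vol < thr$volume_high
  keep[is.na(keep)] <- FALSE
  if (!quiet) {
    message("qc_filter: removed ", sum(!keep), " of ", length(keep),
            " records")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict analysis to the embryonic region
#'
#' Sets `in_region` by centroid membership in a 3D boolean mask (the in
#' silico analogue of manually cropping away the mural trophectoderm).
#' Downstream statistics use `in_region = TRUE` rows only.
#'
#' @param table Embryo table.
#' @param roi_mask Logical array `(z, y, x)`, same shape as the source stack.
#' @param pixel_size_um,z_step_um Calibration used to map centroids back to
#'   voxel indices.
#' @return Table with `in_region` updated.
#' @export
apply_region <- function(table, roi_mask, pixel_size_um, z_step_um) {
  stopifnot(is.logical(roi_mask), length(dim(roi_mask)) == 3L)
  if (nrow(table) == 0) return(table)
  d <- dim(roi_mask)
  iz <- clip(round(table$z_um / z_step_um) + 1, 1, d[1])
  iy <- clip(round(table$y_um / pixel_size_um) + 1, 1, d[2])
  ix <- clip(round(table$x_um / pixel_size_um) + 1, 1, d[3])
  table$in_region <- roi_mask[cbind(iz, iy, ix)]
  table
}

#' Export an embryo table to CSV (lossless round trip)
#'
#' One line per 3D object, with the fixed column order documented in
#' [measure_nuclei()]. Doubles are written with 17 significant digits so the
#' file reads back to bit-identical values.
#'
#' @param table Embryo table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read an embryo table written by [export_table()]
#' @param path CSV path.
#' @return Embryo table data frame.
#' @export
read_embryo_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) > 0 && "in_region" %in% names(tab)) {
    tab$in_region <- as.logical(tab$in_region)
  }
  int_cols <- intersect(c("nucleus_id", "voxel_count"), names(tab))
  for (nm in int_cols) tab[[nm]] <- as.integer(tab[[nm]])
  dbl_cols <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                      int_cols)
  for (nm in dbl_cols) tab[[nm]] <- as.double(tab[[nm]])
  chr_cols <- intersect(c("embryo_id", "stage", "genotype", "record_id"),
                        names(tab))
  for (nm in chr_cols) tab[[nm]] <- as.character(tab[[nm]])
  tab
}
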