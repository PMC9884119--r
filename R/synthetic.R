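#' Specification of a synthetic blastocyst-like embryo stack
#'
#' Describes one simulated confocal acquisition: trophectoderm (TE) nuclei on
#' a spherical shell, an inner-cell-mass cluster (epiblast + primitive
#' endoderm) displaced toward the embryonic pole, per-lineage marker
#' amplitudes, anisotropic z-sampling, shot + read noise and 8-bit
#' quantization. The same spec (including `seed`) always renders the
#' identical stack.
#'
#' Nuclei are anisotropic Gaussian blobs truncated at 2.5 sigma. The visible
#' xy radius is `nucleus_radius_um` (taken as 2 x sigma_xy) and the axial
#' extent is stretched by `z_elongation`, a geometry chosen so that, under
#' the default acquisition calibration, per-slice detection areas fall inside
#' the (5, 30) um^2 window and axial spans exceed 5 optical sections — i.e.
#' the planted objects are consistent with the area and duration filters
#' the segmentation defaults apply.
#'
#' @param stage Stage label (`"E3.5"`, `"E4.5"`, `"diapause"`).
#' @param n_epi,n_pre,n_te Nuclei per lineage (epiblast, primitive endoderm,
#'   trophectoderm).
#' @param nucleus_radius_um Mean visible xy radius, micrometres.
#' @param nucleus_radius_sd_um SD of the per-nucleus radius draw.
#' @param z_elongation Ratio sigma_z / sigma_xy (axial stretch).
#' @param embryo_radius_um Radius of the TE shell.
#' @param icm_offset_um 3-vector (x, y, z) displacing the ICM cluster centre
#'   from the embryo centre; its direction defines the embryonic pole used
#'   for the region-of-interest hemisphere.
#' @param icm_cluster_radius_um Radius of the (z-flattened) ellipsoid
#'   containing EPI/PrE centres.
#' @param icm_z_flatten Ratio of the ICM cluster's z semi-axis to its xy
#'   radius. Flattening keeps ICM nuclei from stacking along the optical
#'   axis, the regime segmentation-by-z-linking assumes.
#' @param min_sep_um Minimum xy-projected centre-to-centre distance between
#'   nuclei whose axial separation is below `z_clear_um`.
#' @param z_clear_um Axial distance beyond which two nuclei may share xy
#'   position (greater than the full axial blob extent plus one section, so
#'   their detection columns cannot touch).
#' @param pixel_size_um xy pixel size.
#' @param z_step_um Optical section spacing (default 2).
#' @param slice_shape `(height, width)` in pixels; default 256 x 256 keeps
#'   desk-scale runs fast, 1024 x 1024 reproduces the acquisition frame.
#' @param n_slices Number of optical sections.
#' @param channel_profiles Profile map (default [default_profiles()] for
#'   `stage`).
#' @param noise List `photon_scale` (variance of shot noise per unit signal)
#'   and `read_sd` (Gaussian read noise SD); set both 0 to disable noise.
#' @param seed Integer seed.
#' @return An object of class `SyntheticEmbryoSpec`.
#' @export
synthetic_embryo_spec <- function(stage = "E3.5",
                                  n_epi = 6, n_pre = 5, n_te = 16,
                                  nucleus_radius_um = 2.7,
                                  nucleus_radius_sd_um = 0.08,
                                  z_elongation = 3.2,
                                  embryo_radius_um = 30,
                                  icm_offset_um = c(14, 0, 0),
                                  icm_cluster_radius_um = 11,
                                  icm_z_flatten = 0.35,
                                  min_sep_um = 5,
                                  z_clear_um = 22,
                                  pixel_size_um = 0.4,
                                  z_step_um = 2,
                                  slice_shape = c(256, 256),
                                  n_slices = 40,
                                  channel_profiles = NULL,
                                  noise = list(photon_scale = 0.5, read_sd = 2),
                                  seed = 1) {
  check_stage(stage)
  stopifnot(n_epi >= 0, n_pre >= 0, n_te >= 0)
  stopifnot(nucleus_radius_um > 0, embryo_radius_um > 0,
            pixel_size_um > 0, z_step_um > 0, n_slices >= 1)
  stopifnot(length(slice_shape) == 2, all(slice_shape >= 8))
  stopifnot(length(icm_offset_um) == 3)
  spec <- list(
    stage = stage, n_epi = as.integer(n_epi), n_pre = as.integer(n_pre),
    n_te = as.integer(n_te),
    nucleus_radius_um = nucleus_radius_um,
    nucleus_radius_sd_um = nucleus_radius_sd_um,
    z_elongation = z_elongation,
    embryo_radius_um = embryo_radius_um,
    icm_offset_um = as.numeric(icm_offset_um),
    icm_cluster_radius_um = icm_cluster_radius_um,
    icm_z_flatten = icm_z_flatten,
    min_sep_um = min_sep_um, z_clear_um = z_clear_um,
    pixel_size_um = pixel_size_um, z_step_um = z_step_um,
    slice_shape = as.integer(slice_shape), n_slices = as.integer(n_slices),
    channel_profiles = channel_profiles %||% default_profiles(stage),
    noise = noise, seed = as.integer(seed)
  )
  class(spec) <- "SyntheticEmbryoSpec"
  spec
}

# Rejection-sample nucleus centres: TE on the shell, ICM in a z-flattened
# interior ellipsoid. A candidate is accepted when every existing centre is
# either >= min_sep_um away in xy projection or >= z_clear_um away axially
# (so no two detection columns can merge). Errors if packing fails within
# bounded retries.
place_centres <- function(spec, centre_um) {
  for (attempt in seq_len(20L)) {
    res <- try(place_centres_once(spec, centre_um), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("could not place nuclei without overlap after bounded retries; ",
       "reduce counts or min_sep_um", call. = FALSE)
}

place_centres_once <- function(spec, centre_um) {
  max_try <- 2000L
  pts <- matrix(numeric(0), ncol = 3)
  sep_ok <- function(p) {
    if (nrow(pts) == 0) return(TRUE)
    dxy <- sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
    dz <- abs(pts[, 3] - p[3])
    all(dxy >= spec$min_sep_um | dz >= spec$z_clear_um)
  }
  add_point <- function(gen) {
    for (i in seq_len(max_try)) {
      p <- gen()
      if (sep_ok(p)) {
        pts <<- rbind(pts, p)
        return(invisible(NULL))
      }
    }
    stop("packing attempt failed", call. = FALSE)
  }
  gen_shell <- function() {
    v <- stats::rnorm(3)
    centre_um + spec$embryo_radius_um * v / sqrt(sum(v^2))
  }
  icm_centre <- centre_um + spec$icm_offset_um
  gen_ball <- function() {
    repeat {
      v <- stats::runif(3, -1, 1)
      if (sum(v^2) <= 1) {
        v[3] <- v[3] * spec$icm_z_flatten
        return(icm_centre + spec$icm_cluster_radius_um * v)
      }
    }
  }
  lineage <- character(0)
  for (i in seq_len(spec$n_te)) { add_point(gen_shell); lineage <- c(lineage, "TE") }
  for (i in seq_len(spec$n_epi)) { add_point(gen_ball); lineage <- c(lineage, "EPI") }
  for (i in seq_len(spec$n_pre)) { add_point(gen_ball); lineage <- c(lineage, "PrE") }
  list(centres = pts, lineage = lineage)
}

#' Render a synthetic embryo stack with ground truth
#'
#' Places nuclei (TE on a spherical shell, EPI/PrE in an interior cluster
#' with a minimum centre-to-centre distance), renders each as an anisotropic
#' Gaussian blob truncated at 2.5 sigma per channel, scaled by a
#' lineage-and-channel amplitude draw from the spec's profiles; adds
#' Poisson-scaled shot noise and Gaussian read noise; clips and quantizes to
#' the spec's bit depth. Also emits the "embryonic region" ROI: the
#' hemisphere toward the ICM pole, emulating the manual crop that removes
#' most of the mural trophectoderm.
#'
#' @param spec A [synthetic_embryo_spec()].
#' @return List with elements `stack` (an `ImageStack` of integer voxels),
#'   `truth` (data frame: `nucleus_id`, `lineage`, true centroid in um, true
#'   truncation-ellipsoid volume in um^3, per-channel amplitude `amp_<ch>`
#'   and pre-noise rendered `total_<ch>`), and `roi` (logical array
#'   `(z, y, x)`).
#' @export
render_stack <- function(spec) {
  stopifnot(inherits(spec, "SyntheticEmbryoSpec"))
  ny <- spec$slice_shape[1]; nx <- spec$slice_shape[2]; nz <- spec$n_slices
  chans <- names(spec$channel_profiles)
  nc <- length(chans)
  px <- spec$pixel_size_um; dz <- spec$z_step_um
  centre_um <- c((nx - 1) / 2 * px, (ny - 1) / 2 * px, (nz - 1) / 2 * dz)

  with_seed(spec$seed, {
    n_total <- spec$n_epi + spec$n_pre + spec$n_te
    field <- array(0, dim = c(nz, ny, nx, nc))
    truth <- data.frame(
      nucleus_id = integer(0), lineage = character(0),
      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
      sigma_xy_um = numeric(0), sigma_z_um = numeric(0),
      volume_um3 = numeric(0), stringsAsFactors = FALSE
    )
    for (ch in chans) {
      truth[[paste0("amp_", ch)]] <- numeric(0)
      truth[[paste0("total_", ch)]] <- numeric(0)
    }

    if (n_total > 0) {
      placed <- place_centres(spec, centre_um)
      radii <- stats::rnorm(n_total, spec$nucleus_radius_um,
                            spec$nucleus_radius_sd_um)
      radii <- pmax(radii, 0.5 * spec$nucleus_radius_um)
      amps <- matrix(0, n_total, nc, dimnames = list(NULL, chans))
      for (lin in c("TE", "EPI", "PrE")) {
        idx <- which(placed$lineage == lin)
        if (length(idx) > 0) {
          amps[idx, ] <- sample_amplitudes(spec$channel_profiles, lin,
                                           length(idx))
        }
      }

      xs <- (seq_len(nx) - 1) * px
      ys <- (seq_len(ny) - 1) * px
      zs <- (seq_len(nz) - 1) * dz
      rows <- vector("list", n_total)
      for (i in seq_len(n_total)) {
        cc <- placed$centres[i, ]
        sxy <- radii[i] / 2
        sz <- sxy * spec$z_elongation
        xr <- which(abs(xs - cc[1]) <= 2.5 * sxy)
        yr <- which(abs(ys - cc[2]) <= 2.5 * sxy)
        zr <- which(abs(zs - cc[3]) <= 2.5 * sz)
        if (length(xr) == 0 || length(yr) == 0 || length(zr) == 0) {
          rows[[i]] <- NULL
          next
        }
        dx2 <- ((xs[xr] - cc[1]) / sxy)^2
        dy2 <- ((ys[yr] - cc[2]) / sxy)^2
        dz2 <- ((zs[zr] - cc[3]) / sz)^2
        m2 <- outer(dz2, outer(dy2, dx2, `+`), `+`)  # (z, y, x)
        blob <- exp(-m2 / 2)
        blob[m2 > 6.25] <- 0
        unit_sum <- sum(blob)
        for (ci in seq_len(nc)) {
          field[zr, yr, xr, ci] <- field[zr, yr, xr, ci] + amps[i, ci] * blob
        }
        row <- data.frame(
          nucleus_id = i, lineage = placed$lineage[i],
          x_um = cc[1], y_um = cc[2], z_um = cc[3],
          sigma_xy_um = sxy, sigma_z_um = sz,
          volume_um3 = 4 / 3 * pi * (2.5 * sxy)^2 * (2.5 * sz),
          stringsAsFactors = FALSE
        )
        for (ch in chans) {
          row[[paste0("amp_", ch)]] <- amps[i, ch]
          row[[paste0("total_", ch)]] <- amps[i, ch] * unit_sum
        }
        rows[[i]] <- row
      }
      truth <- do.call(rbind, c(list(truth), Filter(Negate(is.null), rows)))
    }

    nvox <- length(field)
    ph <- spec$noise$photon_scale %||% 0
    rd <- spec$noise$read_sd %||% 0
    if (ph > 0) {
      field <- field + stats::rnorm(nvox, 0, sqrt(ph * pmax(field, 0)))
    }
    if (rd > 0) {
      field <- field + stats::rnorm(nvox, 0, rd)
    }
    data <- array(as.integer(round(clip(field, 0, 255))),
                  dim = c(nz, ny, nx, nc))
    stack <- image_stack(data, px, dz, chans, bit_depth = 8L)

    u <- spec$icm_offset_um
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else c(1, 0, 0)
    xs <- (seq_len(nx) - 1) * px - centre_um[1]
    ys <- (seq_len(ny) - 1) * px - centre_um[2]
    zs <- (seq_len(nz) - 1) * dz - centre_um[3]
    proj <- outer(zs * u[3], outer(ys * u[2], xs * u[1], `+`), `+`)
    roi <- proj >= 0

    list(stack = stack, truth = truth, roi = roi)
  })
}

#' Generate a cohort of synthetic embryos across stages
#'
#' Renders `n_per_stage` embryos for each of the three stages, with
#' per-embryo sub-seeds derived deterministically from `seed` and
#' stage-appropriate default profiles (unless `base_spec` carries explicit
#' ones).
#'
#' @param n_per_stage Embryos per stage (>= 1).
#' @param base_spec Template [synthetic_embryo_spec()]; its stage, seed and
#'   profiles are replaced per embryo.
#' @param seed Master cohort seed.
#' @param stages Stage labels to include (default all three).
#' @param keep_profiles If `TRUE`, use `base_spec$channel_profiles` for every
#'   stage (a "null" cohort with no stage effect).
#' @param vary_counts Draw per-embryo lineage counts from Poisson
#'   distributions with the base spec's counts as means (default), so
#'   cohorts show the embryo-to-embryo variation in cell number real data
#'   have. Draws are truncated to the geometric packing envelope of the
#'   spec (ICM nuclei must fit the cluster disc at the minimum separation,
#'   TE nuclei the shell), so rendering cannot fail on an unlucky draw.
#' @return List of embryos, each a list with `stack`, `truth`, `roi`,
#'   `stage`, `embryo_id`, `seed`, `spec`.
#' @export
make_cohort <- function(n_per_stage, base_spec = synthetic_embryo_spec(),
                        seed = 1, stages = stage_levels(),
                        keep_profiles = FALSE, vary_counts = TRUE) {
  stopifnot(n_per_stage >= 1)
  # packing envelope: hexagonal-density bound on the ICM disc, empirical
  # shell density for the TE at the default separation
  icm_cap <- max(1, floor(pi * base_spec$icm_cluster_radius_um^2 /
                            (sqrt(3) / 2 * base_spec$min_sep_um^2) * 0.75))
  te_cap <- max(1, floor(20 * (base_spec$embryo_radius_um / 30)^2 *
                           (5 / base_spec$min_sep_um)^2))
  out <- list()
  k <- 0L
  for (st in stages) {
    check_stage(st)
    for (i in seq_len(n_per_stage)) {
      k <- k + 1L
      spec <- base_spec
      spec$stage <- st
      spec$seed <- sub_seed(seed, k)
      if (!keep_profiles) spec$channel_profiles <- default_profiles(st)
      if (vary_counts) {
        cnt <- with_seed(sub_seed(spec$seed, 7777), {
          stats::rpois(3, c(base_spec$n_epi, base_spec$n_pre,
                            base_spec$n_te))
        })
        cnt[3] <- min(cnt[3], te_cap)
        while (cnt[1] + cnt[2] > icm_cap) {
          j <- which.max(cnt[1:2])
          cnt[j] <- cnt[j] - 1L
        }
        spec$n_epi <- cnt[1]; spec$n_pre <- cnt[2]; spec$n_te <- cnt[3]
      }
      emb <- render_stack(spec)
      emb$stage <- st
      emb$embryo_id <- sprintf("%s_%02d", st, i)
      emb$seed <- spec$seed
      emb$spec <- spec
      out[[k]] <- emb
    }
  }
  out
}

#' Write a cohort to disk (stacks, ROIs, ground truth, manifest)
#'
#' One multi-channel TIFF + sidecar per embryo, a single-channel ROI TIFF, a
#' ground-truth CSV, and a cohort manifest CSV (`embryo_id`, `stage`,
#' `genotype`, paths, seed) that [run_pipeline()] consumes.
#'
#' @param cohort Output of [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(emb) {
    stack_path <- file.path(dir, paste0(emb$embryo_id, "_stack.tif"))
    roi_path <- file.path(dir, paste0(emb$embryo_id, "_roi.tif"))
    truth_path <- file.path(dir, paste0(emb$embryo_id, "_truth.csv"))
    write_stack(emb$stack, stack_path)
    write_roi(emb$roi, roi_path)
    utils::write.csv(emb$truth, truth_path, row.names = FALSE)
    data.frame(
      embryo_id = emb$embryo_id, stage = emb$stage, genotype = "WT",
      stack_path = stack_path, roi_path = roi_path, seed = emb$seed,
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
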