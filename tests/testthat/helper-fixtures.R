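# Shared fixtures: tiny stacks and toy tables, all generated in code.

# A small, fast spec for tests that render voxels.
tiny_spec <- function(...) {
  defaults <- list(
    n_epi = 3, n_pre = 2, n_te = 6,
    embryo_radius_um = 18, icm_offset_um = c(9, 0, 0),
    icm_cluster_radius_um = 7,
    slice_shape = c(128, 128), n_slices = 30
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_embryo_spec, args)
}

# Single isolated nucleus, noise off: the cleanest measurable object.
one_nucleus_spec <- function(seed = 7, amp = 100) {
  profiles <- default_profiles("E3.5")
  for (ch in names(profiles)) {
    profiles[[ch]]$EPI <- c(meanlog = log(amp), sdlog = 0)
  }
  synthetic_embryo_spec(
    stage = "E3.5", n_epi = 1, n_pre = 0, n_te = 0,
    icm_offset_um = c(0, 0, 0), icm_cluster_radius_um = 0.001,
    slice_shape = c(96, 96), n_slices = 30,
    channel_profiles = profiles,
    noise = list(photon_scale = 0, read_sd = 0),
    seed = seed
  )
}

# Render a synthetic 2D Gaussian blob on a slice (for detector tests).
blob_slice <- function(ny = 96, nx = 96, cx = 48, cy = 48, sigma = 3.5,
                       amp = 1) {
  xs <- seq_len(nx) - cx
  ys <- seq_len(ny) - cy
  amp * exp(-outer(ys^2, xs^2, "+") / (2 * sigma^2))
}

# Minimal detection object for linker tests.
make_det <- function(slice, x, y, idx = 1L, npx = 25, mean_dna = 100) {
  list(slice_index = as.integer(slice), idx = as.integer(idx), npx = npx,
       area_um2 = npx * 0.16, cx_um = x, cy_um = y, mean_dna = mean_dna)
}

# Toy embryo table with explicit feature values.
toy_table <- function(intden_py705, intden_nanog = NULL,
                      in_region = TRUE, embryo_id = "e1",
                      stage = "diapause") {
  n <- length(intden_py705)
  df <- data.frame(
    embryo_id = rep_len(embryo_id, n),
    nucleus_id = seq_len(n),
    x_um = seq_len(n), y_um = seq_len(n), z_um = seq_len(n),
    voxel_count = rep(10L, n), volume_um3 = rep(300, n),
    intden_py705 = intden_py705,
    intden_nanog = intden_nanog %||% rev(intden_py705),
    in_region = rep_len(in_region, n),
    stage = rep_len(stage, n),
    genotype = "WT",
    stringsAsFactors = FALSE
  )
  df$record_id <- paste(df$embryo_id, df$nucleus_id, sep = ":")
  df
}

# Winding-number point-in-polygon oracle, independent of the package's
# crossing-number implementation. Boundary points are classified inside via
# an exact on-segment test.
winding_inside <- function(px, py, v) {
  n <- nrow(v)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      cr <- (v[j, 1] - v[i, 1]) * (y - v[i, 2]) -
        (v[j, 2] - v[i, 2]) * (x - v[i, 1])
      if (cr == 0 &&
          x >= min(v[i, 1], v[j, 1]) && x <= max(v[i, 1], v[j, 1]) &&
          y >= min(v[i, 2], v[j, 2]) && y <= max(v[i, 2], v[j, 2])) {
        return(TRUE)
      }
    }
    total <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a1 <- atan2(v[i, 2] - y, v[i, 1] - x)
      a2 <- atan2(v[j, 2] - y, v[j, 1] - x)
      da <- a2 - a1
      if (da > pi) da <- da - 2 * pi
      if (da < -pi) da <- da + 2 * pi
      total <- total + da
    }
    abs(total) > pi
  }, logical(1))
}

# Exhaustive two-sample rank-sum p-value by enumerating all group
# assignments of the pooled sample (no-ties instances only).
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  mu <- m * (n + 1) / 2
  combs <- utils::combn(n, m)
  stats <- colSums(matrix(r[combs], nrow = m))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Direct evaluation of the Kruskal-Wallis rank formula (with tie
# correction), independent of stats::kruskal.test.
kw_direct <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(ri) length(ri) * mean(ri)^2, numeric(1))) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
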