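#' Default per-lineage intensity profiles for a developmental stage
#'
#' Per-nucleus peak amplitudes (8-bit units) are drawn from lognormal
#' distributions, one per lineage x channel; positive support and right skew
#' match immunofluorescence readouts. The stage-dependent locations encode
#' the biology the pipeline is meant to resolve:
#'
#' * pY705 (active STAT3) and TFCP2L1 in the epiblast: diapause > E3.5 > E4.5
#'   (both decline during blastocyst expansion and intensify in diapause);
#' * NANOG in the epiblast is reduced at E4.5 (transiently lost around
#'   implantation) relative to E3.5 and diapause;
#' * the trophectoderm is low for every marker at every stage, which is what
#'   makes pooled per-nucleus distributions bimodal;
#' * DAPI is lineage- and stage-independent.
#'
#' Absolute scales are free parameters of the simulation (no reference data
#' pin them); override any entry to change them.
#'
#' @param stage One of `"E3.5"`, `"E4.5"`, `"diapause"`.
#' @return Named list `channel -> lineage -> c(meanlog, sdlog)` with channels
#'   `dapi`, `nanog`, `py705`, `tfcp2l1` and lineages `EPI`, `PrE`, `TE`.
#' @export
#' @examples
#' p <- default_profiles("diapause")
#' exp(p$py705$EPI[["meanlog"]]) # typical epiblast pY705 peak amplitude
default_profiles <- function(stage) {
  check_stage(stage)
  ln <- function(m, s) c(meanlog = log(m), sdlog = s)
  dapi <- list(EPI = ln(240, 0.06), PrE = ln(240, 0.06), TE = ln(240, 0.06))
  epi_py705 <- switch(stage, diapause = 160, E3.5 = 110, E4.5 = 55)
  pre_py705 <- switch(stage, diapause = 80, E3.5 = 60, E4.5 = 35)
  epi_tfcp <- switch(stage, diapause = 150, E3.5 = 100, E4.5 = 50)
  pre_tfcp <- switch(stage, diapause = 70, E3.5 = 55, E4.5 = 35)
  epi_nanog <- switch(stage, diapause = 140, E3.5 = 140, E4.5 = 45)
  list(
    dapi = dapi,
    nanog = list(EPI = ln(epi_nanog, 0.3), PrE = ln(20, 0.4), TE = ln(12, 0.4)),
    py705 = list(EPI = ln(epi_py705, 0.35), PrE = ln(pre_py705, 0.35),
                 TE = ln(15, 0.4)),
    tfcp2l1 = list(EPI = ln(epi_tfcp, 0.35), PrE = ln(pre_tfcp, 0.35),
                   TE = ln(15, 0.4))
  )
}

#' Draw per-nucleus channel amplitudes for a lineage
#'
#' The single code path through which both stack rendering and table-level
#' simulations obtain nucleus intensities.
#'
#' @param profiles Profile map from [default_profiles()].
#' @param lineage `"EPI"`, `"PrE"` or `"TE"`.
#' @param n Number of nuclei.
#' @return Numeric matrix `n x channels` of peak amplitudes.
#' @export
sample_amplitudes <- function(profiles, lineage, n) {
  chans <- names(profiles)
  out <- matrix(0, nrow = n, ncol = length(chans),
                dimnames = list(NULL, chans))
  for (ch in chans) {
    pp <- profiles[[ch]][[lineage]]
    if (is.null(pp)) stop("profile missing lineage ", lineage, call. = FALSE)
    out[, ch] <- stats::rlnorm(n, pp[["meanlog"]], pp[["sdlog"]])
  }
  out
}

#' Simulate a per-nucleus integrated-density table without rendering voxels
#'
#' Draws lineage compositions and amplitudes exactly as [render_stack()]
#' would and converts them to integrated densities with a fixed geometric
#' factor (the voxel sum of the unit-amplitude nucleus blob). Useful for
#' statistical calibration studies where voxel rendering adds nothing.
#'
#' @param stage Stage label.
#' @param n_epi,n_pre,n_te Expected nuclei per lineage. With
#'   `vary_counts = TRUE` (default) the realized counts are Poisson draws
#'   with these means, emulating the embryo-to-embryo variation in lineage
#'   composition real cohorts show; with fixed counts every simulated group
#'   would share an identical lineage mixture, which makes pooled rank tests
#'   conservative under the null.
#' @param vary_counts Draw per-lineage counts from Poisson distributions.
#' @param mural_te_frac Expected fraction of TE nuclei lying outside the
#'   embryonic region (the mural hemisphere removed by cropping); those
#'   records get `in_region = FALSE`. EPI/PrE are always in-region.
#' @param profiles Optional profile map (default [default_profiles()] for
#'   `stage`).
#' @param seed Integer seed.
#' @param embryo_id Identifier placed on every row.
#' @param blob_sum Geometric factor converting peak amplitude to integrated
#'   density (default matches the default nucleus geometry).
#' @return Data frame with `embryo_id`, `stage`, `lineage`, `in_region` and
#'   one `intden_<channel>` column per channel.
#' @export
simulate_intensity_table <- function(stage, n_epi = 6, n_pre = 5, n_te = 16,
                                     vary_counts = TRUE,
                                     mural_te_frac = 0.5,
                                     profiles = NULL, seed = 1,
                                     embryo_id = "sim", blob_sum = 420) {
  check_stage(stage)
  profiles <- profiles %||% default_profiles(stage)
  with_seed(seed, {
    if (vary_counts) {
      counts <- stats::rpois(3, c(n_epi, n_pre, n_te))
      n_epi <- counts[1]; n_pre <- counts[2]; n_te <- counts[3]
    }
    lineages <- rep(c("EPI", "PrE", "TE"), c(n_epi, n_pre, n_te))
    amp_list <- list(
      if (n_epi > 0) sample_amplitudes(profiles, "EPI", n_epi),
      if (n_pre > 0) sample_amplitudes(profiles, "PrE", n_pre),
      if (n_te > 0) sample_amplitudes(profiles, "TE", n_te)
    )
    amps <- do.call(rbind, Filter(Negate(is.null), amp_list))
    df <- data.frame(
      embryo_id = embryo_id,
      nucleus_id = seq_along(lineages),
      stage = stage,
      lineage = lineages,
      in_region = lineages != "TE" |
        stats::runif(length(lineages)) >= mural_te_frac,
      stringsAsFactors = FALSE
    )
    if (length(lineages) > 0) {
      for (ch in colnames(amps)) {
        df[[paste0("intden_", ch)]] <- amps[, ch] * blob_sum
      }
    }
    df$record_id <- paste(df$embryo_id, df$nucleus_id, sep = ":")
    df
  })
}
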