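#' Match measured nuclei to planted ground truth
#'
#' Greedy one-to-one assignment by 3D centroid distance: truth entries are
#' visited in order of their nearest free candidate and matched when that
#' candidate lies within `radius_um`. Used to score segmentation against
#' the generator's ground truth.
#'
#' @param table Embryo table (measured nuclei).
#' @param truth Ground-truth data frame from [render_stack()].
#' @param radius_um Match radius; a sensible default is the planted nucleus
#'   radius.
#' @return List: `n_true`, `n_found`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, and `pairs` (data frame `truth_row`, `table_row`,
#'   `dist_um`).
#' @export
match_to_truth <- function(table, truth, radius_um = 2.7) {
  nt <- nrow(truth); nf <- nrow(table)
  if (nt == 0 || nf == 0) {
    f1 <- if (nt == 0 && nf == 0) 1 else 0
    return(list(n_true = nt, n_found = nf, tp = 0L, fp = nf, fn = nt,
                precision = if (nf > 0) 0 else 1,
                recall = if (nt > 0) 0 else 1, f1 = f1,
                pairs = data.frame(truth_row = integer(0),
                                   table_row = integer(0),
                                   dist_um = numeric(0))))
  }
  D <- sqrt(outer(truth$x_um, table$x_um, "-")^2 +
              outer(truth$y_um, table$y_um, "-")^2 +
              outer(truth$z_um, table$z_um, "-")^2)
  used <- rep(FALSE, nf)
  pairs <- list()
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (length(j) == 1 && is.finite(D[i, j]) && D[i, j] < radius_um) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        truth_row = i, table_row = j, dist_um = D[i, j]
      )
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(truth_row = integer(0), table_row = integer(0),
               dist_um = numeric(0))
  tp <- nrow(pairs)
  precision <- if (nf > 0) tp / nf else 1
  recall <- if (nt > 0) tp / nt else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  list(n_true = nt, n_found = nf, tp = as.integer(tp),
       fp = as.integer(nf - tp), fn = as.integer(nt - tp),
       precision = precision, recall = recall, f1 = f1, pairs = pairs)
}

#' Score planted-nucleus recovery over a synthetic cohort
#'
#' Runs segmentation + measurement + QC on every embryo of a cohort and
#' scores the result against ground truth: pooled detection F1, per-embryo
#' count error, and the correlation between ground-truth total signal and
#' measured integrated density over matched nuclei.
#'
#' @param cohort Output of [make_cohort()].
#' @param params [seg_params()].
#' @param thr [qc_thresholds()].
#' @param channel Channel used for the truth-vs-measured correlation.
#' @param match_radius_um Match radius passed to [match_to_truth()].
#' @return List: `f1`, `precision`, `recall`, `count_errors` (per-embryo
#'   relative errors), `max_count_error`, `intden_cor` (Pearson r),
#'   `n_matched`, `tables` (pooled QC-passed embryo table).
#' @export
evaluate_recovery <- function(cohort, params = seg_params(),
                              thr = qc_thresholds(), channel = "py705",
                              match_radius_um = NULL) {
  tp <- 0L; fp <- 0L; fn <- 0L
  count_errors <- numeric(0)
  truth_sig <- numeric(0); meas_sig <- numeric(0)
  tables <- list()
  for (emb in cohort) {
    radius <- match_radius_um %||% emb$spec$nucleus_radius_um
    seg <- segment_stack(emb$stack, params)
    tab <- measure_nuclei(seg$labels, emb$stack, embryo_id = emb$embryo_id,
                          stage = emb$stage)
    tab <- apply_region(tab, emb$roi, emb$stack$pixel_size_um,
                        emb$stack$z_step_um)
    tab <- qc_filter(tab, thr)
    m <- match_to_truth(tab, emb$truth, radius)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    count_errors <- c(count_errors,
                      abs(nrow(tab) - nrow(emb$truth)) /
                        max(1, nrow(emb$truth)))
    tcol <- paste0("total_", channel)
    mcol <- paste0("intden_", channel)
    if (nrow(m$pairs) > 0 && tcol %in% names(emb$truth) &&
        mcol %in% names(tab)) {
      truth_sig <- c(truth_sig, emb$truth[[tcol]][m$pairs$truth_row])
      meas_sig <- c(meas_sig, tab[[mcol]][m$pairs$table_row])
    }
    tables[[emb$embryo_id]] <- tab
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 1
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  pooled <- do.call(rbind, tables)
  rownames(pooled) <- NULL
  list(
    f1 = f1, precision = precision, recall = recall,
    count_errors = count_errors, max_count_error = max(count_errors),
    intden_cor = if (length(truth_sig) >= 3) {
      stats::cor(truth_sig, meas_sig)
    } else {
      NA_real_
    },
    n_matched = as.integer(tp), tables = pooled
  )
}
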