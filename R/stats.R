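#' Build a one-row test-result record
#' @keywords internal
stat_result <- function(test, groups, statistic, p_value, n_per_group) {
  data.frame(
    test = test,
    groups = paste(groups, collapse = " vs "),
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    n = paste(n_per_group, collapse = "/"),
    label = significance_label(p_value),
    stringsAsFactors = FALSE
  )
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test with midrank tie handling. The p-value is computed by exact
#' enumeration when the smaller sample has at most 8 observations and the
#' pooled data carry no ties, and by the tie-corrected normal approximation
#' (no continuity correction) otherwise. The reported statistic is the
#' Mann-Whitney U for the first sample.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative Only `"two.sided"` (stage comparisons in this
#'   pipeline are two-sided).
#' @param exact_max Largest min-sample size for which the exact distribution
#'   is used (default 8).
#' @return One-row data frame: `test`, `groups`, `statistic`, `p_value`,
#'   `n`, `label`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided",
                              exact_max = 8) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample", call. = FALSE)
  alternative <- match.arg(alternative, "two.sided")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = use_exact, correct = FALSE
  ))
  p <- min(wt$p.value, 1)
  stat_result("wilcoxon", c("x", "y"), unname(wt$statistic), p,
              c(length(x), length(y)))
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' H statistic with tie correction, p from the chi-square distribution with
#' k - 1 df. All-tied data degenerate to H = 0, p = 1 by convention.
#'
#' @param groups List of at least two nonempty numeric vectors (names used
#'   as group labels).
#' @return One-row result data frame as in [wilcoxon_rank_sum()].
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("empty group", call. = FALSE)
  }
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(stat_result("kruskal_wallis", labels, 0, 1,
                       vapply(groups, length, integer(1))))
  }
  g <- factor(rep(labels, vapply(groups, length, integer(1))),
              levels = labels)
  kt <- stats::kruskal.test(values, g)
  stat_result("kruskal_wallis", labels, unname(kt$statistic),
              min(kt$p.value, 1), vapply(groups, length, integer(1)))
}

#' Levene's test for equality of variances (Brown-Forsythe default)
#'
#' ANOVA on absolute deviations from the group centres; the default centre
#' is the group median (Brown-Forsythe variant, robust for the skewed
#' intensity data this pipeline produces), with the mean-centred classic
#' form available.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 observations.
#' @param center `"median"` (default) or `"mean"`.
#' @return One-row result data frame.
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2)) {
    stop("levene_test needs >= 2 groups of >= 2 observations", call. = FALSE)
  }
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, integer(1))),
              levels = labels)
  centre_fun <- if (center == "median") stats::median else mean
  lt <- car::leveneTest(values, g, center = centre_fun)
  stat_result("levene", labels, lt[1, "F value"], min(lt[1, "Pr(>F)"], 1),
              vapply(groups, length, integer(1)))
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, not constant.
#' @param group Label recorded on the result row.
#' @return One-row result data frame with the W statistic.
#' @export
shapiro_test <- function(x, group = "x") {
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("shapiro_test requires 3 <= n <= 5000", call. = FALSE)
  }
  st <- stats::shapiro.test(x)
  stat_result("shapiro", group, unname(st$statistic), min(st$p.value, 1), n)
}

#' Map a p-value to its significance star label
#'
#' `ns` for p > 0.05; `*` for p <= 0.05; `**` for p <= 0.01; `***` for
#' p <= 0.001; `****` for p <= 0.0001 — the most stringent satisfied
#' threshold wins.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp <= 1e-4) "****"
    else if (pp <= 1e-3) "***"
    else if (pp <= 0.01) "**"
    else if (pp <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare per-nucleus marker levels across developmental stages
#'
#' The group-comparison battery applied to integrated densities: Levene
#' (Brown-Forsythe) and per-group Shapiro-Wilk diagnostics, one
#' Kruskal-Wallis test across all stages, and all pairwise two-sided
#' Wilcoxon rank-sum tests. The unit of analysis is the nucleus, pooled
#' across embryos within a stage (as the source workflow plots them);
#' `per_embryo = TRUE` switches to per-embryo means, which avoids the
#' pseudo-replication of pooling at the cost of power. Only QC-passed,
#' in-region records should be supplied; rows with `in_region = FALSE` are
#' dropped here.
#'
#' @param tables One combined embryo table or a list of per-embryo tables.
#' @param channel Channel name (e.g. `"py705"`) or full column name
#'   (e.g. `"intden_py705"`).
#' @param per_embryo Aggregate to per-embryo means before testing.
#' @param adjust P-value adjustment for the pairwise Wilcoxon family:
#'   `"none"` (default, matching unadjusted pairwise reporting) or any
#'   method of [stats::p.adjust()], e.g. `"holm"`.
#' @return List of class `stage_comparison`: `results` (stacked result
#'   rows), `summaries` (per-stage n, quartiles, mean — violin-ready), and
#'   `values` (named list of the vectors compared).
#' @export
compare_stages <- function(tables, channel, per_embryo = FALSE,
                           adjust = "none") {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  col <- if (channel %in% names(tab)) channel else paste0("intden_", channel)
  if (!col %in% names(tab)) {
    stop("channel column not found: ", col, call. = FALSE)
  }
  tab <- tab[!is.na(tab$stage) & tab$in_region, , drop = FALSE]
  stages <- intersect(stage_levels(), unique(tab$stage))
  if (length(stages) < 2) {
    stop("need records from at least 2 stages", call. = FALSE)
  }
  if (per_embryo) {
    agg <- stats::aggregate(tab[[col]],
                            by = list(stage = tab$stage,
                                      embryo_id = tab$embryo_id),
                            FUN = mean)
    values <- split(agg$x, factor(agg$stage, levels = stages))
  } else {
    values <- split(tab[[col]], factor(tab$stage, levels = stages))
  }
  if (any(vapply(values, length, integer(1)) == 0)) {
    stop("a stage has 0 records", call. = FALSE)
  }

  res <- list(levene_test(values))
  for (st in stages) {
    v <- values[[st]]
    if (length(v) > 5000) v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
    if (length(v) >= 3 && length(unique(v)) > 1) {
      res[[length(res) + 1L]] <- shapiro_test(v, group = st)
    }
  }
  res[[length(res) + 1L]] <- kruskal_wallis(values)
  pair_rows <- list()
  for (i in seq_len(length(stages) - 1)) {
    for (j in seq((i + 1), length(stages))) {
      r <- wilcoxon_rank_sum(values[[stages[i]]], values[[stages[j]]])
      r$groups <- paste(stages[i], "vs", stages[j])
      pair_rows[[length(pair_rows) + 1L]] <- r
    }
  }
  if (adjust != "none" && length(pair_rows) > 0) {
    ps <- vapply(pair_rows, `[[`, numeric(1), "p_value")
    padj <- stats::p.adjust(ps, method = adjust)
    for (k in seq_along(pair_rows)) {
      pair_rows[[k]]$p_value <- padj[k]
      pair_rows[[k]]$label <- significance_label(padj[k])
    }
  }
  results <- do.call(rbind, c(res, pair_rows))
  rownames(results) <- NULL

  summaries <- do.call(rbind, lapply(stages, function(st) {
    v <- values[[st]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stage = st, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v), mean = mean(v),
               stringsAsFactors = FALSE)
  }))

  structure(list(results = results, summaries = summaries, values = values,
                 channel = col, per_embryo = per_embryo),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat("Stage comparison on", x$channel,
      if (x$per_embryo) "(per-embryo means)" else "(per-nucleus)", "\n\n")
  print(x$summaries, row.names = FALSE)
  cat("\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}
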