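# Rank-based statistics: exactness, identities, invariances, labelling.

test_that("Wilcoxon exact p matches enumeration on the canonical example", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)          # 2 / choose(6, 3)
  expect_equal(r$p_value, perm_wilcox_p(c(1, 2, 3), c(4, 5, 6)))
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("identical samples give the null-mean statistic and p = 1", {
  x <- c(1, 2, 3, 4)
  r <- wilcoxon_rank_sum(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)  # U at its null mean
  expect_equal(r$p_value, 1)
})

test_that("exact Wilcoxon p equals the exhaustive-permutation oracle for all small sizes", {
  set.seed(77)
  for (m in 2:6) {
    for (n in 2:6) {
      for (rep in 1:3) {
        x <- sample(100, m); y <- sample(100 + seq(101, 200), n)
        # regenerate until no ties across the pooled sample
        while (anyDuplicated(c(x, y)) > 0) {
          x <- runif(m); y <- runif(n)
        }
        expect_equal(wilcoxon_rank_sum(x, y)$p_value, perm_wilcox_p(x, y),
                     tolerance = 1e-12,
                     info = sprintf("m=%d n=%d rep=%d", m, n, rep))
      }
    }
  }
})

test_that("large-sample Wilcoxon p agrees with a Monte-Carlo permutation oracle", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(45, 0.4)
  p_pkg <- wilcoxon_rank_sum(x, y)$p_value
  pooled <- c(x, y); m <- length(x)
  r <- rank(pooled); mu <- m * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(m)]) - mu)
  B <- 1e5
  stat <- replicate(B, abs(sum(sample(r, m)) - mu))
  p_mc <- mean(stat >= obs - 1e-9)
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(p_pkg - p_mc), 4 * se + 0.002)
})

test_that("Kruskal-Wallis H matches direct evaluation of the rank formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_wallis(groups)
  expect_equal(r$statistic, kw_direct(groups), tolerance = 1e-12)
  set.seed(8)
  g2 <- list(rnorm(7), rnorm(5, 1), rnorm(9, -0.5), rnorm(4))
  expect_equal(kruskal_wallis(g2)$statistic, kw_direct(g2), tolerance = 1e-10)
  # degenerate all-tied convention
  r0 <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank-sum statistic", {
  set.seed(12)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  kw <- kruskal_wallis(list(x, y))
  w <- wilcoxon_rank_sum(x, y)      # normal approximation, no continuity corr.
  z2 <- stats::qnorm(w$p_value / 2)^2
  expect_equal(kw$statistic, z2, tolerance = 1e-8)
  expect_equal(kw$p_value, stats::pchisq(z2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(kw$p_value, w$p_value, tolerance = 1e-8)
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(3)
  groups <- list(rexp(8), rexp(6, 0.5), rexp(10, 2))
  h0 <- kruskal_wallis(groups)$statistic
  for (f in list(function(v) v^3, function(v) log(v + 1e-9),
                 function(v) exp(v), function(v) 5 * v - 2)) {
    expect_equal(kruskal_wallis(lapply(groups, f))$statistic, h0,
                 tolerance = 1e-10)
  }
})

test_that("Levene statistic is zero for identical groups and ~zero for shifted copies", {
  g <- c(1, 3, 5, 7, 9)
  expect_equal(levene_test(list(g, g))$statistic, 0)
  r <- levene_test(list(g, g + 100, g - 50))
  expect_lt(r$statistic, 1e-20)
  expect_equal(r$p_value, 1, tolerance = 1e-6)
  expect_error(levene_test(list(1, 2)), ">= 2")
})

test_that("Shapiro-Wilk wrapper enforces size bounds and rejects constants", {
  set.seed(4)
  r <- shapiro_test(rnorm(50))
  expect_gt(r$statistic, 0)
  expect_lte(r$statistic, 1)
  expect_error(shapiro_test(c(1, 2)), "3 <= n")
  expect_error(shapiro_test(rep(1, 10)))
})

test_that("significance labels follow the star threshold mapping", {
  expect_equal(significance_label(c(0.2, 0.05, 0.03, 0.01, 0.001, 1e-5)),
               c("ns", "*", "*", "**", "***", "****"))
  expect_equal(significance_label(5e-5), "****")
  # step function, monotone in stringency
  ps <- sort(runif(50))
  labs <- significance_label(ps)
  ranks <- match(labs, c("****", "***", "**", "*", "ns"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("compare_stages runs the full battery and flags planted effects", {
  tabs <- do.call(rbind, lapply(seq_len(6), function(i) {
    st <- rep(stage_levels(), each = 2)[i]
    simulate_intensity_table(st, seed = 100 + i,
                             embryo_id = sprintf("%s_%d", st, i))
  }))
  cmp <- compare_stages(tabs, "py705")
  expect_s3_class(cmp, "stage_comparison")
  expect_setequal(unique(cmp$results$test),
                  c("levene", "shapiro", "kruskal_wallis", "wilcoxon"))
  expect_equal(nrow(cmp$summaries), 3)
  expect_equal(sum(cmp$results$test == "wilcoxon"), 3)
  dia_e45 <- cmp$results[cmp$results$test == "wilcoxon" &
                           grepl("E4.5", cmp$results$groups) &
                           grepl("diapause", cmp$results$groups), ]
  expect_true(dia_e45$label %in% c("*", "**", "***", "****"))
  # single-stage input errors
  expect_error(compare_stages(tabs[tabs$stage == "E3.5", ], "py705"),
               "2 stages")
  # per-embryo mode aggregates to one value per embryo (2 per stage here,
  # so the variance diagnostic sits on a near-perfect fit and warns)
  cmp2 <- suppressWarnings(compare_stages(tabs, "py705", per_embryo = TRUE))
  expect_equal(unname(vapply(cmp2$values, length, integer(1))), rep(2L, 3))
  # holm adjustment never lowers a p-value
  cmp3 <- compare_stages(tabs, "py705", adjust = "holm")
  expect_true(all(cmp3$results$p_value[cmp3$results$test == "wilcoxon"] >=
                    cmp$results$p_value[cmp$results$test == "wilcoxon"]))
})
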