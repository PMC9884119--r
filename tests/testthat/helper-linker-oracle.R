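# Brute-force z-linking oracle: per consecutive slice pair, enumerate every
# matching whose links all respect the gating distance, keep the maximum
# cardinality, and among those the minimum total distance. An instance
# qualifies for greedy-vs-optimal comparison when that optimum is unique and
# all its links are mutual nearest neighbours.

enum_matchings <- function(n1, n2) {
  out <- list(list())
  for (i in seq_len(n1)) {
    new <- list()
    for (m in out) {
      new[[length(new) + 1L]] <- m  # i unmatched
      usedj <- vapply(m, `[[`, numeric(1), 2)
      for (j in setdiff(seq_len(n2), usedj)) {
        new[[length(new) + 1L]] <- c(m, list(c(i, j)))
      }
    }
    out <- new
  }
  out
}

oracle_pairs <- function(a, b, maxd) {
  D <- as.matrix(stats::dist(rbind(a, b)))
  D <- D[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE]
  best <- NULL; best_card <- -1L; best_cost <- Inf; unique_best <- TRUE
  for (m in enum_matchings(nrow(a), nrow(b))) {
    if (length(m) == 0) {
      cost <- 0; card <- 0L
    } else {
      ij <- do.call(rbind, m)
      if (any(D[ij] > maxd)) next
      cost <- sum(D[ij]); card <- nrow(ij)
    }
    if (card > best_card || (card == best_card && cost < best_cost - 1e-12)) {
      best <- m; best_card <- card; best_cost <- cost; unique_best <- TRUE
    } else if (card == best_card && abs(cost - best_cost) <= 1e-12 &&
               !identical(m, best)) {
      unique_best <- FALSE
    }
  }
  mutual <- TRUE
  for (pr in best) {
    i <- pr[1]; j <- pr[2]
    if (which.min(D[i, ]) != j || which.min(D[, j]) != i) mutual <- FALSE
  }
  list(pairs = best, unique = unique_best, mutual = mutual, D = D)
}

# Run one randomized comparison; returns TRUE if the instance qualified (and
# asserts equality), FALSE if it was skipped.
check_linker_instance <- function(max_per_slice = 6, max_slices = 4,
                                  maxd = 5, box = 20) {
  n_slices <- sample(2:max_slices, 1)
  counts <- sample(seq_len(max_per_slice), n_slices, replace = TRUE)
  pts <- lapply(counts, function(k) cbind(runif(k, 0, box), runif(k, 0, box)))
  expected_links <- vector("list", n_slices - 1)
  for (s in seq_len(n_slices - 1)) {
    o <- oracle_pairs(pts[[s]], pts[[s + 1]], maxd = maxd)
    if (!o$unique || !o$mutual) return(FALSE)
    expected_links[[s]] <- o$pairs
  }
  dbs <- lapply(seq_len(n_slices), function(s) {
    lapply(seq_len(counts[s]), function(k) {
      make_det(s - 1, pts[[s]][k, 1], pts[[s]][k, 2])
    })
  })
  tr <- link_z(dbs, seg_params(min_track_len = 1, max_link_dist_um = maxd))
  got_set <- character(0)
  for (t in tr) {
    ds <- t$detections
    if (length(ds) < 2) next
    for (q in seq_len(length(ds) - 1)) {
      s <- ds[[q]]$slice_index + 1
      i <- which(pts[[s]][, 1] == ds[[q]]$cx_um &
                   pts[[s]][, 2] == ds[[q]]$cy_um)
      j <- which(pts[[s + 1]][, 1] == ds[[q + 1]]$cx_um &
                   pts[[s + 1]][, 2] == ds[[q + 1]]$cy_um)
      got_set <- c(got_set, paste(s, i, j))
    }
  }
  exp_set <- character(0)
  for (s in seq_len(n_slices - 1)) {
    for (pr in expected_links[[s]]) {
      exp_set <- c(exp_set, paste(s, pr[1], pr[2]))
    }
  }
  testthat::expect_setequal(got_set, exp_set)
  TRUE
}
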