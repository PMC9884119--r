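#' Threshold gate on a single channel
#'
#' Selects records with integrated density strictly above `min_intden`
#' ("above" is strict: a record exactly at the cut is not selected).
#'
#' @param channel Channel name or full column name.
#' @param min_intden Threshold (>= 0).
#' @return A `Gate` object.
#' @export
gate_threshold <- function(channel, min_intden) {
  stopifnot(min_intden >= 0)
  structure(list(kind = "threshold", channel = channel,
                 min_intden = min_intden), class = "Gate")
}

#' Polygon gate in a 2D co-expression space
#'
#' Selects records whose `(x_channel, y_channel)` point lies inside a closed
#' polygon; points on an edge or vertex count as inside (documented
#' convention). The polygon must have at least 3 vertices and be
#' non-self-intersecting.
#'
#' @param x_channel,y_channel Channel names or full column names.
#' @param vertices Numeric matrix (or 2-column data frame) of ordered
#'   vertices.
#' @return A `Gate` object.
#' @export
gate_polygon <- function(x_channel, y_channel, vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("polygon needs a numeric n x 2 vertex matrix with n >= 3",
         call. = FALSE)
  }
  if (polygon_self_intersects(vertices)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  structure(list(kind = "polygon", x_channel = x_channel,
                 y_channel = y_channel, vertices = vertices),
            class = "Gate")
}

# Proper-crossing check between all non-adjacent edge pairs.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1 else i + 1, ])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq((i + 2), n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      si <- seg(i); sj <- seg(j)
      if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-polygon membership (boundary-inclusive)
#'
#' Crossing-number (even-odd) test with an explicit on-boundary check:
#' points lying exactly on an edge or vertex are inside.
#'
#' @param px,py Coordinates of the query points.
#' @param vertices Ordered polygon vertex matrix (n x 2).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    # boundary check: collinear and within the segment's bounding box
    on_edge <- any(
      (xe - xs) * (y - ys) - (ye - ys) * (x - xs) == 0 &
        x >= pmin(xs, xe) & x <= pmax(xs, xe) &
        y >= pmin(ys, ye) & y <= pmax(ys, ye)
    )
    if (on_edge) return(TRUE)
    # even-odd ray cast (half-open in y to count vertices once)
    crossing <- (ys > y) != (ye > y)
    if (!any(crossing)) return(FALSE)
    xint <- xs[crossing] +
      (y - ys[crossing]) / (ye[crossing] - ys[crossing]) *
        (xe[crossing] - xs[crossing])
    sum(xint > x) %% 2 == 1
  }, logical(1))
}

resolve_feature <- function(table, channel) {
  col <- if (channel %in% names(table)) channel else paste0("intden_", channel)
  if (!col %in% names(table)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  table[[col]]
}

#' Apply a gate to an embryo table
#'
#' @param table Embryo table (QC-passed records).
#' @param gate A `Gate` from [gate_threshold()] or [gate_polygon()].
#' @return Character vector of selected `record_id`s (stable under record
#'   reordering).
#' @export
gate_select <- function(table, gate) {
  stopifnot(inherits(gate, "Gate"))
  if (nrow(table) == 0) return(character(0))
  if (gate$kind == "threshold") {
    v <- resolve_feature(table, gate$channel)
    sel <- v > gate$min_intden
  } else {
    vx <- resolve_feature(table, gate$x_channel)
    vy <- resolve_feature(table, gate$y_channel)
    sel <- point_in_polygon(vx, vy, gate$vertices)
  }
  table$record_id[sel]
}

#' Reconstruct an "in silico embryo" point cloud
#'
#' One point per record: nucleus centroid in physical um, the colour value
#' of the chosen channel, and a `selected` flag from a gate selection.
#' Serializable to CSV for any 3D scatter viewer.
#'
#' @param table Embryo table (typically QC-passed).
#' @param colour_channel Channel whose value colours each point.
#' @param selection Character vector of selected record ids (e.g. from
#'   [gate_select()]).
#' @return Data frame of class `insilico_embryo`: `record_id`, `embryo_id`,
#'   `stage`, `x_um`, `y_um`, `z_um`, `colour_value`, `selected`.
#' @export
reconstruct <- function(table, colour_channel, selection = character(0)) {
  pts <- data.frame(
    record_id = table$record_id,
    embryo_id = table$embryo_id,
    stage = table$stage,
    x_um = table$x_um, y_um = table$y_um, z_um = table$z_um,
    colour_value = resolve_feature(table, colour_channel),
    selected = table$record_id %in% selection,
    stringsAsFactors = FALSE
  )
  class(pts) <- c("insilico_embryo", "data.frame")
  pts
}

#' Spatial enrichment of a gated selection in the embryonic region
#'
#' Quantifies how strongly gated cells concentrate in the embryonic
#' compartment: the fraction of selected cells in-region divided by the
#' fraction of all cells in-region, with a one-sided hypergeometric p-value
#' for over-representation. The p-value is an added quantification beyond
#' the visual claim the reconstruction supports.
#'
#' @param table Embryo table.
#' @param selection Character vector of selected record ids.
#' @return List: `n_selected`, `frac_selected_in_region`,
#'   `frac_all_in_region`, `enrichment_ratio` (NA with a note when nothing
#'   is selected), `p_hypergeometric`.
#' @export
region_enrichment <- function(table, selection) {
  n <- nrow(table)
  in_reg <- table$in_region
  sel <- table$record_id %in% selection
  k <- sum(sel)
  frac_all <- mean(in_reg)
  if (k == 0) {
    return(list(n_selected = 0L, frac_selected_in_region = NA_real_,
                frac_all_in_region = frac_all,
                enrichment_ratio = NA_real_, p_hypergeometric = NA_real_,
                note = "no cells selected; ratio undefined"))
  }
  k_in <- sum(sel & in_reg)
  frac_sel <- k_in / k
  ratio <- if (frac_all > 0) frac_sel / frac_all else NA_real_
  p <- stats::phyper(k_in - 1, sum(in_reg), n - sum(in_reg), k,
                     lower.tail = FALSE)
  list(n_selected = as.integer(k), frac_selected_in_region = frac_sel,
       frac_all_in_region = frac_all, enrichment_ratio = ratio,
       p_hypergeometric = p)
}

#' Per-embryo summary: cell counts and mean intensities
#'
#' @param tables One combined embryo table or list of tables.
#' @param embryo_ids Optional vector of expected embryo ids; embryos with no
#'   records are reported with `n_cells = 0` and `NA` means.
#' @return Data frame: `embryo_id`, `stage`, `n_cells`, one
#'   `mean_intden_<ch>` per channel.
#' @export
per_embryo_summary <- function(tables, embryo_ids = NULL) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  intden_cols <- grep("^intden_", names(tab), value = TRUE)
  ids <- embryo_ids %||% unique(tab$embryo_id)
  rows <- lapply(ids, function(id) {
    sub <- tab[tab$embryo_id == id, , drop = FALSE]
    row <- data.frame(
      embryo_id = id,
      stage = if (nrow(sub) > 0) sub$stage[1] else NA_character_,
      n_cells = nrow(sub), stringsAsFactors = FALSE
    )
    for (col in intden_cols) {
      row[[paste0("mean_", col)]] <-
        if (nrow(sub) > 0) mean(sub[[col]]) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between embryo size and mean marker level
#'
#' Rank-based (Spearman) by default, consistent with the pipeline's
#' non-parametric statistics; Pearson available.
#'
#' @param summary Output of [per_embryo_summary()].
#' @param channel Channel name (matched against `mean_intden_<channel>`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List: `estimate` (rho or r), `p_value`, `n`, `method`.
#' @export
size_intensity_correlation <- function(summary, channel,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  col <- if (channel %in% names(summary)) channel else
    paste0("mean_intden_", channel)
  if (!col %in% names(summary)) {
    stop("channel column not found: ", col, call. = FALSE)
  }
  ok <- !is.na(summary[[col]]) & summary$n_cells > 0
  ct <- suppressWarnings(stats::cor.test(
    summary$n_cells[ok], summary[[col]][ok],
    method = method, exact = FALSE
  ))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = sum(ok), method = method)
}
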