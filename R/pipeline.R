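#' Default pipeline configuration
#'
#' A single nested configuration carrying every tunable of the pipeline,
#' with defaults equal to the protocol constants (segmentation percentiles,
#' detection and overlap thresholds, unsharp radius/weight, area and
#' duration filters, DAPI and volume QC windows) and documented package
#' choices elsewhere. Serializable to YAML;
#' [read_config()] rejects unknown keys so a typo cannot silently fall back
#' to a default.
#'
#' @return Nested list of class `PipelineConfig`.
#' @export
pipeline_config <- function() {
  structure(list(
    schema_version = 1L,
    segmentation = unclass(seg_params()),
    qc = c(unclass(qc_thresholds()),
           list(dapi_scale = "norm10", volume_units = "um3")),
    stats = list(channels = c("py705", "tfcp2l1", "nanog"),
                 adjust = "none", per_embryo = FALSE),
    gates = list(),
    dna_channel = "dapi",
    seed = 1L
  ), class = "PipelineConfig")
}

#' Write a pipeline configuration to YAML
#' @param config A `PipelineConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else {
    x
  }
}

#' Read and validate a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults; keys not present in the
#' default schema are an error.
#'
#' @param path YAML path.
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass_recursive(pipeline_config())
  merged <- merge_config(base, raw, prefix = "")
  structure(merged, class = "PipelineConfig")
}

merge_config <- function(base, upd, prefix) {
  if (is.null(upd)) return(base)
  unknown <- setdiff(names(upd), names(base))
  if (length(unknown) > 0 && !identical(prefix, "gates.")) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
        !identical(nm, "gates") && !identical(nm, "channels")) {
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]],
                                 prefix = paste0(prefix, nm, "."))
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

config_to_seg_params <- function(config) {
  do.call(seg_params, config$segmentation)
}

config_to_qc <- function(config) {
  q <- config$qc
  list(
    thr = qc_thresholds(q$dapi_mean_low, q$dapi_mean_high,
                        q$volume_low, q$volume_high),
    dapi_scale = q$dapi_scale %||% "norm10",
    volume_units = q$volume_units %||% "um3"
  )
}

#' Read a cohort manifest CSV
#'
#' Columns: `embryo_id`, `stage`, `genotype`, `stack_path`, `roi_path`
#' (optional, may be empty), `seed` (optional). Embryo ids must be unique
#' and stages valid.
#'
#' @param path Manifest CSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("embryo_id", "stage", "stack_path")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(man$embryo_id)) {
    stop("manifest embryo_ids not unique", call. = FALSE)
  }
  bad <- setdiff(unique(man$stage), stage_levels())
  if (length(bad) > 0) {
    stop("manifest has invalid stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"genotype" %in% names(man)) man$genotype <- "WT"
  if (!"roi_path" %in% names(man)) man$roi_path <- ""
  man
}

process_embryo <- function(stack, roi, config, embryo_id, stage, genotype) {
  params <- config_to_seg_params(config)
  seg <- segment_stack(stack, params, dna_channel = config$dna_channel)
  tab <- measure_nuclei(seg$labels, stack, embryo_id = embryo_id,
                        stage = stage, genotype = genotype)
  log <- as.list(seg$log)
  if (!is.null(roi)) {
    tab <- apply_region(tab, roi, stack$pixel_size_um, stack$z_step_um)
  }
  log$measured <- nrow(tab)
  log$in_region <- sum(tab$in_region)
  qc <- config_to_qc(config)
  # crop first, then QC (documented order)
  tab_qc <- qc_filter(tab, qc$thr, dapi_scale = qc$dapi_scale,
                      volume_units = qc$volume_units)
  log$qc_passed <- nrow(tab_qc)
  list(labels = seg$labels, tracks = seg$tracks, table_raw = tab,
       table = tab_qc, log = log)
}

#' Run the full pipeline over a cohort manifest
#'
#' For every embryo: read the stack (and ROI mask if given), segment the DNA
#' channel, measure all nuclei, restrict to the embryonic region, apply QC,
#' and write the label volume and per-object table. Afterwards the cohort
#' tables are pooled for stage statistics, configured gates are applied, and
#' per-embryo summaries with the size-intensity correlation are written. A
#' machine-readable run log records per-stage object counts and any
#' per-embryo failure; failed embryos are skipped, the others complete, and
#' the returned summary carries a nonzero `n_failed`.
#'
#' @param manifest Manifest data frame ([read_manifest()]) or path to one.
#' @param config A `PipelineConfig` (default [pipeline_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list: `tables` (pooled QC-passed table), `stats`
#'   (list of `stage_comparison` per channel), `summary` (per-embryo),
#'   `log`, `n_failed`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()
  logs <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      stack <- read_stack(row$stack_path)
      roi <- if (nzchar(row$roi_path %||% "") && file.exists(row$roi_path)) {
        read_roi(row$roi_path)
      } else {
        NULL
      }
      pe <- process_embryo(stack, roi, config, row$embryo_id, row$stage,
                           row$genotype)
      write_labels(pe$labels,
                   file.path(out_dir, paste0(row$embryo_id, "_labels.tif")))
      export_table(pe$table,
                   file.path(out_dir, paste0(row$embryo_id, "_table.csv")))
      pe
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[row$embryo_id]] <- conditionMessage(res)
    } else {
      tables[[row$embryo_id]] <- res$table
      logs[[row$embryo_id]] <- res$log
    }
  }
  pooled <- if (length(tables) > 0) do.call(rbind, tables) else NULL
  if (!is.null(pooled)) rownames(pooled) <- NULL

  stats_out <- list()
  if (!is.null(pooled) && length(unique(pooled$stage[pooled$in_region])) >= 2) {
    for (ch in config$stats$channels) {
      cmp <- tryCatch(
        compare_stages(pooled, ch, per_embryo = config$stats$per_embryo,
                       adjust = config$stats$adjust),
        error = function(e) NULL
      )
      if (!is.null(cmp)) {
        stats_out[[ch]] <- cmp
        utils::write.csv(cmp$results,
                         file.path(out_dir, paste0("stats_", ch, ".csv")),
                         row.names = FALSE)
        utils::write.csv(cmp$summaries,
                         file.path(out_dir, paste0("violin_", ch, ".csv")),
                         row.names = FALSE)
      }
    }
  }

  if (!is.null(pooled) && length(config$gates) > 0) {
    for (gname in names(config$gates)) {
      g <- config$gates[[gname]]
      gate <- if (identical(g$kind, "polygon")) {
        gate_polygon(g$x_channel, g$y_channel,
                     matrix(unlist(g$vertices), ncol = 2, byrow = TRUE))
      } else {
        gate_threshold(g$channel, g$min_intden)
      }
      sel <- gate_select(pooled, gate)
      utils::write.csv(data.frame(record_id = sel),
                       file.path(out_dir, paste0("gate_", gname, ".csv")),
                       row.names = FALSE)
    }
  }

  summary_tab <- if (!is.null(pooled)) {
    per_embryo_summary(pooled, embryo_ids = setdiff(manifest$embryo_id,
                                                    names(failures)))
  } else {
    NULL
  }
  if (!is.null(summary_tab)) {
    utils::write.csv(summary_tab, file.path(out_dir, "per_embryo_summary.csv"),
                     row.names = FALSE)
    export_table(pooled, file.path(out_dir, "cohort_table.csv"))
  }

  run_log <- list(
    package_version = as.character(utils::packageVersion("blastocyto")),
    n_embryos = nrow(manifest),
    n_failed = length(failures),
    failures = failures,
    counts = logs
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_config(config, file.path(out_dir, "config_used.yaml"))

  invisible(list(tables = pooled, stats = stats_out, summary = summary_tab,
                 log = run_log, n_failed = length(failures)))
}
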