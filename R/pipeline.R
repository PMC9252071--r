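#' Validate a quantification run configuration
#'
#' The configuration (YAML file or equivalent list) names the images,
#' their channel-role TIFFs, the pixel size, the ROI polygon file, the
#' metrics to compute and optional parameter overrides. Unknown keys are
#' rejected and all referenced files must exist.
#'
#' @param config Path to a YAML file or a list.
#' @return The validated configuration list (with defaults filled in).
#' @export
validate_quantify_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config)
    config <- yaml::read_yaml(config)
  }
  allowed <- c("pixel_size_um", "roi_file", "metrics", "params", "images")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  required <- c("pixel_size_um", "roi_file", "metrics", "images")
  miss <- setdiff(required, names(config))
  if (length(miss)) stop("missing config keys: ",
                         paste(miss, collapse = ", "))
  known_metrics <- c("plaque_burden", "mex04_ratio",
                     "neuritic_damage_ratio", "microglia_coverage",
                     "plaque_associated_microglia", "cd68_in_microglia",
                     "background_subtracted_intensity",
                     "tau_epitope_ratio")
  bad <- setdiff(unlist(config$metrics), known_metrics)
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "))
  if (!file.exists(config$roi_file)) {
    stop("ROI file not found: ", config$roi_file)
  }
  p <- config$params %||% list()
  pu <- setdiff(names(p), c("min_plaque_area_um2", "neurite_halo_um",
                            "microglia_assoc_halo_um"))
  if (length(pu)) stop("unknown params keys: ", paste(pu, collapse = ", "))
  config$params <- do.call(plaque_params, p)
  for (img in config$images) {
    iu <- setdiff(names(img), c("id", "regions", "channels"))
    if (length(iu)) stop("unknown image keys: ",
                         paste(iu, collapse = ", "))
    if (is.null(img$id) || is.null(img$regions) || is.null(img$channels)) {
      stop("each image needs id, regions and channels")
    }
    ru <- setdiff(names(img$channels), channel_roles())
    if (length(ru)) stop("unknown channel roles: ",
                         paste(ru, collapse = ", "))
    for (f in unlist(img$channels)) {
      if (!file.exists(f)) stop("channel TIFF not found: ", f)
    }
  }
  config
}

metric_channel_needs <- list(
  plaque_burden = "plaque_6e10",
  mex04_ratio = c("plaque_mex04", "plaque_6e10"),
  neuritic_damage_ratio = c("plaque_6e10", "lamp1", "microglia"),
  microglia_coverage = "microglia",
  plaque_associated_microglia = c("plaque_6e10", "microglia"),
  cd68_in_microglia = c("cd68", "microglia"),
  background_subtracted_intensity = "microglia",
  tau_epitope_ratio = c("tau_phospho", "tau_total")
)

compute_metric <- function(metric, stacks, region, params) {
  switch(metric,
    plaque_burden =
      plaque_burden(stacks$plaque_6e10, region, params),
    mex04_ratio =
      mex04_ratio(stacks$plaque_mex04, stacks$plaque_6e10, region),
    neuritic_damage_ratio =
      neuritic_damage_ratio(stacks$plaque_6e10, stacks$lamp1,
                            stacks$microglia, region, params),
    microglia_coverage =
      microglia_coverage(stacks$microglia, region),
    plaque_associated_microglia =
      plaque_associated_microglia(stacks$plaque_6e10, stacks$microglia,
                                  region, params),
    cd68_in_microglia =
      cd68_in_microglia(stacks$cd68, stacks$microglia, region),
    background_subtracted_intensity =
      background_subtracted_intensity(stacks$microglia, region),
    tau_epitope_ratio =
      tau_epitope_ratio(stacks$tau_phospho, stacks$tau_total, region),
    stop("unknown metric: ", metric)
  )
}

#' Run the image quantification pipeline
#'
#' For every configured image and region, computes the requested metrics
#' and writes a long-format CSV report (`image, region, metric, value,
#' flag`) plus a machine-readable run manifest (config hash, package
#' version, per-image status). Per-image failures are recorded and
#' skipped; the function errors only if every image fails.
#'
#' @param config YAML path or configuration list (see
#'   [validate_quantify_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the metric report `data.frame`.
#' @export
run_quantify <- function(config, out_dir) {
  config <- validate_quantify_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rois <- read_roi_json(config$roi_file)
  rows <- list()
  status <- list()
  for (img in config$images) {
    res <- tryCatch({
      stacks <- lapply(stats::setNames(names(img$channels),
                                       names(img$channels)),
                       function(role) {
        read_stack_tiff(img$channels[[role]], config$pixel_size_um, role)
      })
      for (region_name in unlist(img$regions)) {
        if (is.null(rois[[region_name]])) {
          stop("region not in ROI file: ", region_name)
        }
        for (metric in unlist(config$metrics)) {
          need <- metric_channel_needs[[metric]]
          if (!all(need %in% names(stacks))) {
            stop(sprintf("metric %s needs channels: %s", metric,
                         paste(need, collapse = ", ")))
          }
          out <- compute_metric(metric, stacks, rois[[region_name]],
                                config$params)
          rows[[length(rows) + 1L]] <-
            metric_report_rows(img$id, region_name, metric, out)
        }
      }
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    status[[img$id]] <- res
    if (res != "ok") message(sprintf("image %s %s", img$id, res))
  }
  if (!any(unlist(status) == "ok")) stop("all images failed")
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  manifest <- list(
    tool = "microquant",
    version = as.character(utils::packageVersion("microquant")),
    config_hash = config_hash(config),
    images = status
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  # params may be a classed object; serialize plainly
  config$params <- unclass(config$params)
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the single-cell QC and marker pipeline
#'
#' Loads a count matrix and labels, applies [qc_filter()], log-normalizes,
#' computes cluster proportions (when cluster labels are present) and the
#' marker table between two configured groups, and writes
#' `qc_report.csv`, `markers.csv` and `proportions.csv`.
#'
#' @param config YAML path or list with keys `counts` (MTX directory or
#'   CSV), `labels` (CSV), optional `qc` and `markers` parameter blocks,
#'   and `compare` (`list(group_a =, group_b =)`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the three tables.
#' @export
run_scrna <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config)
    config <- yaml::read_yaml(config)
  }
  allowed <- c("counts", "labels", "qc", "markers", "compare")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (is.null(config$counts)) stop("missing config key: counts")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cm <- read_counts(config$counts, config$labels)
  qcp <- do.call(qc_params, config$qc %||% list())
  mkp <- do.call(marker_params, config$markers %||% list())
  qc <- qc_filter(cm, qcp)
  utils::write.csv(qc$report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)

  filtered <- qc$matrix
  norm <- log_normalize(filtered, mkp$scale_factor)

  markers <- NULL
  if (!is.null(config$compare)) {
    ga <- config$compare$group_a; gb <- config$compare$group_b
    a <- which(filtered$cell_group == ga)
    b <- which(filtered$cell_group == gb)
    if (length(a) == 0L || length(b) == 0L) {
      stop("comparison groups not found after QC")
    }
    markers <- wilcoxon_markers(norm, a, b, mkp)
    utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                     row.names = FALSE)
  }

  props <- NULL
  if (!is.null(filtered$cell_cluster)) {
    props <- cluster_proportions(filtered$cell_cluster,
                                 filtered$cell_group)
    utils::write.csv(props, file.path(out_dir, "proportions.csv"),
                     row.names = FALSE)
  }
  invisible(list(qc_report = qc$report, markers = markers,
                 proportions = props))
}
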