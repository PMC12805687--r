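# Group-level statistics and end-to-end pipeline orchestration.

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-tailed rank-sum test: exact p-value when n1*n2 <= 400 and there are
#' no ties, normal approximation with continuity correction otherwise.
#' The U statistic is reported for the first group.
#'
#' @param a,b numeric vectors, both nonempty.
#' @param variable optional name of the compared variable (for printing).
#' @param exact_max largest n1*n2 for which the exact distribution is used.
#' @return A list of class `group_comparison`: `U`, `p_value`, `n`,
#'   `medians`, `variable`.
#' @export
mann_whitney <- function(a, b, variable = NULL, exact_max = 400) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stopf("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 n = c(a = length(a), b = length(b)),
                 medians = c(a = median(a), b = median(b)),
                 exact = exact, variable = variable),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison>%s U = %g, two-tailed p = %.4g ",
                     "(%s)\n  n = %d vs %d, medians %.4g vs %.4g\n"),
              if (is.null(x$variable)) "" else paste0(" ", x$variable, ":"),
              x$U, x$p_value,
              if (x$exact) "exact" else "normal approximation",
              x$n[1], x$n[2], x$medians[1], x$medians[2]))
  invisible(x)
}

default_config <- function() {
  list(phantom = NULL, input = NULL, seed = 1L,
       segment = list(enabled = FALSE, method = "otsu", noise_sd = 0),
       instances = list(),
       epithelium_enabled = TRUE,
       cortex_depth = 1000, neighbor_radius = 40, cluster_threshold = 10,
       virtslice = list(thickness_um = 4, interval = 10, start = 10,
                        n_analyzed = 5, visibility_floor_um = 5,
                        axis = "z"))
}

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  modifyList(default_config(), config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates phantom generation (or volume loading), optional
#' intensity-based segmentation, instance extraction, cortex geometry,
#' depth/neighbor/density morphometrics, and the virtual-histology
#' comparison, writing a CSV + JSON report bundle. Identical config and
#' seed reproduce identical outputs.
#'
#' @param config a config list, or a path to a YAML/JSON config file.
#'   Recognized blocks: `phantom` (a [phantom_spec()] or its argument
#'   list), `input` (paths: labels, epithelium, tissue, voxel_size),
#'   `segment` (enabled, method, noise_sd), `instances` (arguments of
#'   [instance_params()]), `epithelium_enabled` (FALSE emulates a sample
#'   whose surface epithelium is not visible: depths are skipped and the
#'   density denominator is the tissue volume), `cortex_depth`,
#'   `neighbor_radius`, `cluster_threshold`, `virtslice` (thickness_um,
#'   interval, start, n_analyzed, visibility_floor_um), `seed`.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing files.
#' @return A report bundle (list) with `oocytes`, `summary`, `strategies`,
#'   `group` elements, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)

  truth <- NULL
  if (!is.null(cfg$phantom)) {
    sp <- if (inherits(cfg$phantom, "phantom_spec")) cfg$phantom
          else do.call(phantom_spec, cfg$phantom)
    truth <- stage("phantom", generate_phantom(
      sp, rasterize = isTRUE(cfg$segment$enabled)))
    epithelium <- truth$epithelium_mask
    tissue <- truth$tissue_mask
    voxel_size <- sp$voxel_size
  } else if (!is.null(cfg$input)) {
    lv <- stage("load", read_volume(cfg$input$labels,
                                    voxel_size = cfg$input$voxel_size))
    epithelium <- stage("load", read_volume(
      cfg$input$epithelium, voxel_size = cfg$input$voxel_size))$grid > 0
    tissue <- stage("load", read_volume(
      cfg$input$tissue, voxel_size = cfg$input$voxel_size))$grid > 0
    voxel_size <- lv$voxel_size
  } else stopf("config must name either a 'phantom' spec or 'input' volumes")

  if (isTRUE(cfg$segment$enabled)) {
    img <- stage("render", render_intensity(truth,
                                            noise_sd = cfg$segment$noise_sd,
                                            seed = cfg$seed))
    mask <- stage("segment", threshold_segment(
      img, method = cfg$segment$method, epithelium_mask = epithelium))
    inst <- stage("instances", extract_instances(
      mask, do.call(instance_params, cfg$instances), voxel_size))
    oocytes <- inst$oocytes
  } else if (!is.null(truth)) {
    oocytes <- truth$oocytes
  } else {
    mask <- lv$grid > 0L
    inst <- stage("instances", extract_instances(
      mask, do.call(instance_params, cfg$instances), voxel_size))
    oocytes <- inst$oocytes
  }

  if (isTRUE(cfg$epithelium_enabled)) {
    geom <- stage("cortex", build_cortex(epithelium, tissue, voxel_size,
                                         cfg$cortex_depth))
    oocytes <- stage("depths", oocyte_depths(oocytes, geom))
  } else {
    warning("epithelium disabled: skipping depth measurements; ",
            "density computed over the tissue mask", call. = FALSE)
    d <- dim(tissue)
    layer_counts <- colSums(matrix(tissue, nrow = d[1] * d[2], ncol = d[3]))
    geom <- structure(list(distance_field = NULL, cortex_mask = tissue,
                           cortex_depth = Inf, voxel_size = voxel_size,
                           cortical_volume_mm3 =
                             sum(layer_counts) * voxel_size^3 * 1e-9,
                           layer_volume_um3 = layer_counts * voxel_size^3,
                           dims = d), class = "cortex_geometry")
    oocytes$depth_um <- NULL
  }
  oocytes <- stage("neighbors", neighbor_counts(oocytes,
                                                cfg$neighbor_radius))
  dens <- stage("density", density_3d(oocytes, geom))
  clustered <- stage("clusters", cluster_flags(oocytes,
                                               cfg$cluster_threshold))
  vs <- cfg$virtslice
  strategies <- stage("virtslice", compare_strategies(
    oocytes, geom, thickness = vs$thickness_um, interval = vs$interval,
    five_start = vs$start, n_five = vs$n_analyzed,
    visibility_floor = vs$visibility_floor_um, axis = vs$axis))

  summary <- list(n_oocytes = nrow(oocytes),
                  cortical_volume_mm3 = geom$cortical_volume_mm3,
                  density_per_mm3 = dens,
                  median_depth_um = if ("depth_um" %in% names(oocytes) &&
                                        nrow(oocytes))
                    median(oocytes$depth_um) else NULL,
                  median_neighbor_count = if (nrow(oocytes))
                    median(oocytes$neighbor_count) else NULL,
                  n_clustered = nrow(clustered),
                  seed = cfg$seed)
  bundle <- list(oocytes = oocytes, summary = summary,
                 strategies = strategies, clustered = clustered,
                 geometry = geom, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_oocyte_table(oocytes, file.path(out_dir, "oocytes.csv"))
    write.csv(strategies, file.path(out_dir, "strategies.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(bundle)
}
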