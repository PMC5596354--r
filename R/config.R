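#' Run configuration
#'
#' Bundles every tunable parameter of the workflow. Defaults are the values
#' used throughout the package's validation: a 100-bin intensity grid, LoG
#' filter of half-size 8 px and sigma 0.8 px, background-mask refinement with a
#' disk-5 opening (minimum surviving blob area 50 px^2), disk-10 erosion and
#' filling of interior holes up to 1500 px^2.
#'
#' @param n_bins number of equal-width intensity bins used both for candidate
#'   mask thresholds and for the spot-count threshold grid (>= 2)
#' @param log_hsize LoG kernel size in pixels (>= 3)
#' @param log_sigma LoG Gaussian sigma in pixels (> 0)
#' @param open_min_area minimum blob area (px^2) surviving the opening stage
#' @param erosion_radius disk radius (px) of the erosion stage
#' @param infill_max_hole maximum interior hole area (px^2) filled by the
#'   infill stage
#' @param open_disk_radius disk radius (px) of the opening structuring element
#' @param smooth_sigma sigma (px) of the optional Gaussian smoothing applied to
#'   the masked FISH signal before integration; 0 disables the stage
#' @param connectivity pixel connectivity for blob labeling, 4 or 8
#' @param summary_mode slice summary modes to report: any of `"ALL"`,
#'   `"CENTRAL80"`, `"MAX"`
#' @param gap_factor dominant-gap factor of the near/far cutoff used when
#'   assigning nuclei to ommatidia (see [near_cutoff()])
#' @param plateau_min_frac minimum fraction of the threshold grid a constant
#'   spot-count run must span before [run_spotcount()] accepts it as a genuine
#'   noise-resilient plateau
#' @param drop_border_anchors exclude background blobs touching the image
#'   border from ommatidium anchoring (the inter-ommatidial background web)
#' @param max_cells maximum cells per ommatidium (R8 nuclei are not visible in
#'   the planes this workflow targets, hence 7)
#' @param seed integer seed used by synthetic-data presets run through the CLI
#'
#' @return a list of class `ccrit_config`
#' @export
#' @examples
#' cfg <- run_config(smooth_sigma = 0)  # disable the optional smoothing stage
#' cfg$n_bins
run_config <- function(n_bins = 100L,
                       log_hsize = 8L,
                       log_sigma = 0.8,
                       open_min_area = 50,
                       erosion_radius = 10L,
                       infill_max_hole = 1500,
                       open_disk_radius = 5L,
                       smooth_sigma = 0.8,
                       connectivity = 8L,
                       summary_mode = c("ALL", "CENTRAL80", "MAX"),
                       gap_factor = 3,
                       plateau_min_frac = 0.3,
                       drop_border_anchors = TRUE,
                       max_cells = 7L,
                       seed = 1L) {
  summary_mode <- match.arg(summary_mode, c("ALL", "CENTRAL80", "MAX"),
                            several.ok = TRUE)
  cfg <- list(
    n_bins = as.integer(n_bins),
    log_hsize = as.integer(log_hsize),
    log_sigma = as.numeric(log_sigma),
    open_min_area = as.numeric(open_min_area),
    erosion_radius = as.integer(erosion_radius),
    infill_max_hole = as.numeric(infill_max_hole),
    open_disk_radius = as.integer(open_disk_radius),
    smooth_sigma = as.numeric(smooth_sigma),
    connectivity = as.integer(connectivity),
    summary_mode = summary_mode,
    gap_factor = as.numeric(gap_factor),
    plateau_min_frac = as.numeric(plateau_min_frac),
    drop_border_anchors = isTRUE(drop_border_anchors),
    max_cells = as.integer(max_cells),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "ccrit_config")
}

validate_config <- function(cfg) {
  if (cfg$n_bins < 2L) ccrit_abort("n_bins must be >= 2", "parameter_error")
  if (cfg$log_hsize < 3L) ccrit_abort("log_hsize must be >= 3", "parameter_error")
  pos <- c("log_sigma", "open_min_area", "erosion_radius", "infill_max_hole",
           "open_disk_radius", "gap_factor")
  for (p in pos) {
    if (cfg[[p]] <= 0) ccrit_abort(sprintf("%s must be > 0", p), "parameter_error")
  }
  if (cfg$smooth_sigma < 0) ccrit_abort("smooth_sigma must be >= 0", "parameter_error")
  if (!cfg$connectivity %in% c(4L, 8L)) {
    ccrit_abort("connectivity must be 4 or 8", "parameter_error")
  }
  if (cfg$plateau_min_frac < 0 || cfg$plateau_min_frac > 1) {
    ccrit_abort("plateau_min_frac must be in [0, 1]", "parameter_error")
  }
  if (cfg$max_cells < 1L) ccrit_abort("max_cells must be >= 1", "parameter_error")
  invisible(cfg)
}

#' @export
print.ccrit_config <- function(x, ...) {
  cat("<ccrit_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a run configuration from a flat key/value YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file path
#' @return a `ccrit_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    ccrit_abort(sprintf("config file '%s' not found", path), "io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    ccrit_abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
                "parameter_error")
  }
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param config a `ccrit_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "ccrit_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
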