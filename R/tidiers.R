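# broom-style accessors for the workflow's result objects.

#' Tidy a ccrit result
#'
#' @param x a `ccrit_result`
#' @param ... unused
#' @return the per-slice, per-cell tibble (`ommatidium_label`, `cell_number`,
#'   `slice_index`, `integrated_intensity`)
#' @export
tidy.ccrit_result <- function(x, ...) {
  x$cells
}

#' One-row overview of a ccrit result
#'
#' @param x a `ccrit_result`
#' @param ... unused
#' @return a one-row tibble: ommatidium/cell/slice counts, the selected
#'   background threshold, mean slice noise, and the specimen mean integrated
#'   intensity (cells averaged within ommatidia first)
#' @export
glance.ccrit_result <- function(x, ...) {
  sm <- specimen_mean(x, mode = x$summaries$mode[1])
  tibble::tibble(
    n_ommatidia = length(unique(x$cell_map$ommatidium_label)),
    n_cells = nrow(x$cell_map),
    n_slices = max(x$cells$slice_index),
    n_unassigned = length(attr(x$cell_map, "unassigned")),
    background_threshold = x$masks$background_threshold,
    mean_noise = mean(x$noise$noise),
    mean_intensity = sm$by_ommatidium
  )
}

#' Tidy a spot-count curve
#'
#' @param x a `ccrit_spot_curve`
#' @param ... unused
#' @return tibble with `threshold` and `count`
#' @export
tidy.ccrit_spot_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
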