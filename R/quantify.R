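# Per-cell transcript quantification: digital noise subtraction using the
# refined background mask, nucleus-mask application, optional Gaussian
# smoothing, integration over each assigned cell's nucleus-blob pixels, and
# slice summaries in three modes.

#' Mean background ("noise") intensity of an image
#'
#' @param image 2-D numeric matrix
#' @param background_mask logical matrix with at least one set pixel
#' @return mean intensity over the masked pixels
#' @export
estimate_noise <- function(image, background_mask) {
  check_image(image)
  background_mask <- check_mask(background_mask, "background_mask")
  if (!any(background_mask)) ccrit_abort("background mask is empty", "empty_mask")
  mean(image[background_mask])
}

#' Subtract a noise level, flooring at zero
#'
#' @param image 2-D numeric matrix
#' @param noise non-negative intensity to subtract from every pixel
#' @return matrix of `max(image - noise, 0)`
#' @export
subtract_noise <- function(image, noise) {
  check_image(image)
  if (noise < 0) ccrit_abort("noise must be >= 0", "parameter_error")
  pmax(image - noise, 0)
}

#' Zero out extracellular signal
#'
#' Pixel-wise product with the nucleus mask.
#'
#' @param image 2-D numeric matrix
#' @param nucleus_mask logical matrix of the same shape
#' @return masked image
#' @export
apply_cell_mask <- function(image, nucleus_mask) {
  check_image(image)
  nucleus_mask <- check_mask(nucleus_mask, "nucleus_mask")
  if (!identical(dim(image), dim(nucleus_mask))) {
    ccrit_abort("image and nucleus mask dimensions differ", "dimension_error")
  }
  image * nucleus_mask
}

#' Gaussian-smooth an image
#'
#' Normalised Gaussian convolution with reflective borders; intensity is
#' preserved away from the borders. `sigma = 0` is the identity (the stage is
#' optional in the workflow).
#'
#' @param image 2-D numeric matrix
#' @param sigma smoothing sigma in pixels (>= 0)
#' @return smoothed image
#' @export
smooth_image <- function(image, sigma = 0.8) {
  check_image(image)
  if (sigma < 0) ccrit_abort("sigma must be >= 0", "parameter_error")
  if (sigma == 0) return(image)
  convolve2(image, gaussian_kernel(sigma))
}

#' Integrate intensities over each assigned cell
#'
#' @param image a processed (noise-subtracted, masked, optionally smoothed)
#'   2-D numeric matrix
#' @param cell_map a `cell_map` from [assign_ommatidia()]
#' @return a tibble with `ommatidium_label`, `cell_number`,
#'   `integrated_intensity` (sum of pixel intensities over the cell's
#'   nucleus-blob pixel set)
#' @export
integrate_cells <- function(image, cell_map) {
  check_image(image)
  tibble::tibble(
    ommatidium_label = cell_map$ommatidium_label,
    cell_number = cell_map$cell_number,
    integrated_intensity = unname(purrr::map_dbl(cell_map$pixels, function(p) {
      sum(image[p])
    }))
  )
}

#' Summarise per-slice cell intensities
#'
#' Three reporting modes: `ALL` (mean/sd over every slice), `CENTRAL80`
#' (mean/sd over the central 80 percent of slices, trimming 10 percent from
#' each end: 0-based slice indices `floor(0.1 n) .. ceil(0.9 n) - 1`), and
#' `MAX` (values from the slice whose whole-image processed total is maximal;
#' sd is NA). With fewer than 2 slices `CENTRAL80` falls back to `ALL` with a
#' warning.
#'
#' @param cells per-slice tibble with `ommatidium_label`, `cell_number`,
#'   `slice_index`, `integrated_intensity`
#' @param mode one or more of `"ALL"`, `"CENTRAL80"`, `"MAX"`
#' @param n_slices total slice count
#' @param max_slice index of the maximal-total slice (required for `"MAX"`)
#' @return summary tibble with `ommatidium_label`, `cell_number`, `mode`,
#'   `mean`, `sd`
#' @export
summarize_cells <- function(cells, mode = c("ALL", "CENTRAL80", "MAX"),
                            n_slices = max(cells$slice_index),
                            max_slice = NULL) {
  mode <- match.arg(mode, several.ok = TRUE)
  out <- purrr::map(mode, function(m) {
    sel <- cells
    if (m == "CENTRAL80") {
      if (n_slices < 2L) {
        rlang::warn("CENTRAL80 needs >= 2 slices; falling back to ALL",
                    class = "ccrit_central80_fallback")
      } else {
        keep <- seq(floor(0.1 * n_slices) + 1L, ceiling(0.9 * n_slices))
        sel <- cells[cells$slice_index %in% keep, ]
      }
    }
    if (m == "MAX") {
      if (is.null(max_slice)) {
        ccrit_abort("MAX mode requires `max_slice`", "parameter_error")
      }
      sel <- cells[cells$slice_index == max_slice, ]
      return(dplyr::summarise(
        dplyr::group_by(sel, .data$ommatidium_label, .data$cell_number),
        mode = m, mean = mean(.data$integrated_intensity), sd = NA_real_,
        .groups = "drop"
      ))
    }
    dplyr::summarise(
      dplyr::group_by(sel, .data$ommatidium_label, .data$cell_number),
      mode = m,
      mean = mean(.data$integrated_intensity),
      sd = stats::sd(.data$integrated_intensity),
      .groups = "drop"
    )
  })
  dplyr::bind_rows(out)
}

#' Run the full cell-by-cell integrated-transcript workflow
#'
#' The seven steps in order: (1) MIP of the nuclear channel, (2) 100-bin
#' intensity grouping, (3) nucleus mask and photoreceptor identification,
#' (4) background mask and cell-to-ommatidium assignment, (5) noise
#' subtraction and nucleus-mask application to every FISH slice, (6) optional
#' Gaussian smoothing, (7) per-cell integrated intensities and stack
#' summaries. Deterministic: a pure function of the two stacks and the
#' configuration.
#'
#' @param nucleus_stack nuclear-stain [image_stack]
#' @param fish_stack FISH-channel [image_stack] of the same geometry
#' @param config a [run_config()]
#' @return an object of class `ccrit_result`: list with `cells` (per-slice
#'   tibble), `summaries`, `cell_map`, `masks` (`mask_pair`), `noise`
#'   (per-slice noise estimates), `max_slice`, `config`
#' @export
run_ccrit <- function(nucleus_stack, fish_stack, config = run_config()) {
  stopifnot(inherits(nucleus_stack, "image_stack"), inherits(fish_stack, "image_stack"))
  if (nucleus_stack$height != fish_stack$height ||
      nucleus_stack$width != fish_stack$width ||
      nucleus_stack$n_slices != fish_stack$n_slices) {
    ccrit_abort("nucleus and FISH stacks must share geometry", "dimension_error")
  }

  masks <- with_stage("masking", build_masks(nucleus_stack, config))

  nblobs <- with_stage("masking", label_blobs(masks$nucleus_mask, config$connectivity))
  bblobs <- with_stage("masking", label_blobs(masks$background_mask, config$connectivity))
  anchors <- bblobs
  if (config$drop_border_anchors) {
    interior <- !bblobs$touches_border
    if (any(interior)) anchors <- bblobs[interior, ]
    else ccrit_log("all background blobs touch the border; keeping all as anchors")
  }
  cell_map <- with_stage("assign",
                         assign_ommatidia(anchors, nblobs,
                                          gap_factor = config$gap_factor,
                                          max_cells = config$max_cells))

  processed_totals <- numeric(fish_stack$n_slices)
  noise <- numeric(fish_stack$n_slices)
  cells <- purrr::map(seq_len(fish_stack$n_slices), function(k) {
    img <- fish_stack$slices[[k]]
    nz <- estimate_noise(img, masks$background_mask)
    noise[k] <<- nz
    proc <- apply_cell_mask(subtract_noise(img, nz), masks$nucleus_mask)
    proc <- smooth_image(proc, config$smooth_sigma)
    processed_totals[k] <<- sum(proc)
    dplyr::mutate(integrate_cells(proc, cell_map), slice_index = k,
                  .before = "integrated_intensity")
  })
  cells <- dplyr::bind_rows(cells)
  max_slice <- which.max(processed_totals)
  summaries <- with_stage(
    "quantify",
    summarize_cells(cells, config$summary_mode, fish_stack$n_slices, max_slice)
  )

  structure(
    list(
      cells = cells,
      summaries = summaries,
      cell_map = cell_map,
      masks = masks,
      noise = tibble::tibble(slice_index = seq_along(noise), noise = noise),
      max_slice = max_slice,
      config = config
    ),
    class = "ccrit_result"
  )
}

#' Tag errors with the pipeline stage they came from
#' @noRd
with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    ccrit_error = function(e) {
      e$message <- sprintf("[stage %s] %s", stage, e$message)
      stop(e)
    }
  )
}

#' @export
print.ccrit_result <- function(x, ...) {
  cat(sprintf(
    "<ccrit_result> %d ommatidia, %d cells, %d slices\n",
    length(unique(x$cell_map$ommatidium_label)), nrow(x$cell_map),
    max(x$cells$slice_index)
  ))
  cat(sprintf("  background threshold: %.4g; mean slice noise: %.4g\n",
              x$masks$background_threshold, mean(x$noise$noise)))
  invisible(x)
}

#' Specimen-level mean intensity
#'
#' The stack-level summary used for genotype comparisons. Two averaging
#' orders are reported: `by_ommatidium` first averages cells within each
#' ommatidium, then averages ommatidium means (cells averaged across all
#' ommatidia, then through the stack); `pooled` averages all cell summaries
#' directly.
#'
#' @param result a `ccrit_result`
#' @param mode summary mode to draw from (default `"ALL"`)
#' @return one-row tibble with `by_ommatidium` and `pooled` means
#' @export
specimen_mean <- function(result, mode = "ALL") {
  s <- result$summaries[result$summaries$mode == mode, ]
  if (nrow(s) == 0L) ccrit_abort(sprintf("no summaries for mode %s", mode), "parameter_error")
  per_omm <- dplyr::summarise(dplyr::group_by(s, .data$ommatidium_label),
                              m = mean(.data$mean), .groups = "drop")
  tibble::tibble(by_ommatidium = mean(per_omm$m), pooled = mean(s$mean))
}
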