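# QC graphics: spot-count curves, mask overlays and labeled cell maps.

#' Plot a spot-count curve
#'
#' Spot count against candidate threshold on a log count axis, with the
#' automatically selected plateau threshold marked when it exists.
#'
#' @param object a `ccrit_spot_curve` from [spot_curve()]
#' @param selected optional threshold to mark (e.g. from
#'   [select_plateau_threshold()])
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ccrit_spot_curve <- function(object, selected = NULL, ...) {
  df <- tibble::as_tibble(unclass(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "threshold (intensity)", y = "spot count",
                  title = "Spot-count distribution after LoG filtering") +
    ggplot2::theme_minimal()
  if (!is.null(selected)) {
    sel <- df[which.min(abs(df$threshold - as.numeric(selected))), ]
    p <- p + ggplot2::geom_point(data = sel, colour = "red", size = 2)
  }
  p
}

#' Plot per-cell integrated intensities
#'
#' Mean integrated intensity (ALL mode) per cell, grouped by ommatidium.
#'
#' @param object a `ccrit_result`
#' @param mode summary mode to plot
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ccrit_result <- function(object, mode = "ALL", ...) {
  s <- object$summaries[object$summaries$mode == mode, ]
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$cell_number), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~ommatidium_label) +
    ggplot2::labs(x = "cell", y = sprintf("integrated intensity (%s)", mode),
                  title = "Per-cell integrated transcript intensity") +
    ggplot2::theme_minimal()
}

#' Matrix as a tidy pixel tibble
#' @noRd
image_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot the MIP with mask outlines and labeled cells
#'
#' False-colour MIP with nucleus centroids annotated by ommatidium letter and
#' counter-clockwise cell number, and anchor centroids marked.
#'
#' @param result a `ccrit_result`
#' @param downsample keep every n-th pixel of the MIP raster for speed
#' @return a ggplot
#' @export
plot_cell_map <- function(result, downsample = 2L) {
  mip <- result$masks$mip
  keep_r <- seq(1L, nrow(mip), by = downsample)
  keep_c <- seq(1L, ncol(mip), by = downsample)
  df <- image_df(mip[keep_r, keep_c])
  df$row <- keep_r[df$row]; df$col <- keep_c[df$col]
  cm <- result$cell_map
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = "MIP") +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_point(
      data = tibble::tibble(col = cm$anchor_col, row = cm$anchor_row),
      colour = "white", shape = 3, size = 2
    ) +
    ggplot2::geom_text(
      data = tibble::tibble(
        col = cm$centroid_col, row = cm$centroid_row,
        lab = paste0(cm$ommatidium_label, cm$cell_number)
      ),
      ggplot2::aes(label = .data$lab), colour = "white", size = 2.6
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = "Assigned cells on the nuclear MIP") +
    ggplot2::theme_minimal()
}

#' Plot the nucleus and refined background masks
#'
#' @param masks a `mask_pair` from [build_masks()]
#' @param downsample keep every n-th pixel
#' @return a ggplot
#' @export
plot_masks <- function(masks, downsample = 2L) {
  keep_r <- seq(1L, nrow(masks$mip), by = downsample)
  keep_c <- seq(1L, ncol(masks$mip), by = downsample)
  lab <- matrix("outside", length(keep_r), length(keep_c))
  lab[masks$nucleus_mask[keep_r, keep_c]] <- "nucleus"
  lab[masks$background_mask[keep_r, keep_c]] <- "background"
  df <- image_df(masks$mip[keep_r, keep_c])
  df$region <- as.vector(lab)
  df$row <- keep_r[df$row]; df$col <- keep_c[df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(nucleus = "#fde725",
                                          background = "#31688e",
                                          outside = "grey20")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", title = "Nucleus and background masks") +
    ggplot2::theme_minimal()
}
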