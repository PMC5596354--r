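#' Image stacks
#'
#' An `image_stack` is a z-ordered list of equally-shaped 2-D intensity
#' matrices for one channel of a confocal acquisition, with optional voxel
#' metadata. Intensities are arbitrary units, never rescaled on input;
#' pixel coordinates throughout the package are (row, col) with the origin at
#' the top-left corner.
#'
#' @param slices list of numeric matrices, in acquisition z order
#' @param channel_role `"NUCLEUS"` (nuclear stain, e.g. DAPI) or `"FISH"`
#'   (smFISH/RNAscope probe signal)
#' @param z_step optional slice spacing in micrometres (e.g. 0.65 for the
#'   acquisitions this workflow was designed around)
#' @param pixel_size optional lateral pixel size in micrometres
#'
#' @return an object of class `image_stack` with fields `slices`, `height`,
#'   `width`, `n_slices`, `channel_role`, `z_step`, `pixel_size`
#' @export
#' @examples
#' st <- image_stack(list(matrix(0, 4, 5), matrix(1, 4, 5)), "NUCLEUS")
#' st$n_slices
image_stack <- function(slices, channel_role = c("NUCLEUS", "FISH"),
                        z_step = NULL, pixel_size = NULL) {
  channel_role <- match.arg(channel_role)
  if (!is.list(slices) || length(slices) < 1L) {
    ccrit_abort("`slices` must be a non-empty list of matrices", "format_error")
  }
  slices <- lapply(slices, function(s) {
    check_image(s, "slice")
    storage.mode(s) <- "double"
    s
  })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ccrit_abort("all slices must share the same height and width", "format_error")
  }
  if (any(vapply(slices, function(s) any(!is.finite(s)) || any(s < 0), logical(1)))) {
    ccrit_abort("slice intensities must be finite and >= 0", "format_error")
  }
  structure(
    list(
      slices = slices,
      height = dims[1, 1],
      width = dims[2, 1],
      n_slices = length(slices),
      channel_role = channel_role,
      z_step = z_step,
      pixel_size = pixel_size
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf(
    "<image_stack> %d slice(s) of %d x %d px, channel %s\n",
    x$n_slices, x$height, x$width, x$channel_role
  ))
  if (!is.null(x$z_step)) cat(sprintf("  z step: %g um\n", x$z_step))
  if (!is.null(x$pixel_size)) cat(sprintf("  pixel size: %g um\n", x$pixel_size))
  invisible(x)
}

#' Load an image stack from TIFF
#'
#' Reads either a multi-page grayscale TIFF or a directory of single-page
#' TIFFs taken in lexical filename order as z order. Integer pixel values are
#' kept as stored (no rescaling to \[0, 1\]).
#'
#' @param path a multi-page TIFF file or a directory of single-page TIFFs
#' @param channel_role `"NUCLEUS"` or `"FISH"`
#' @inheritParams image_stack
#' @return an [image_stack]
#' @export
load_stack <- function(path, channel_role = c("NUCLEUS", "FISH"),
                       z_step = NULL, pixel_size = NULL) {
  channel_role <- match.arg(channel_role)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) {
      ccrit_abort(sprintf("no TIFF files found in directory '%s'", path), "io_error")
    }
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    ccrit_abort(sprintf("cannot read '%s'", path), "io_error")
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) {
        ccrit_abort("multi-channel TIFF pages are not supported; supply one stack per channel",
                    "format_error")
      }
      p <- p[, , 1]
    }
    storage.mode(p) <- "double"
    p
  })
  image_stack(pages, channel_role, z_step = z_step, pixel_size = pixel_size)
}

#' Write an image stack to a multi-page TIFF
#'
#' Values are rounded to integers and stored at the requested bit depth, so a
#' write/load round trip is lossless for integer-valued stacks within range.
#'
#' @param stack an [image_stack]
#' @param path output file path
#' @param bits_per_sample 8 or 16
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!bits_per_sample %in% c(8L, 16L)) {
    ccrit_abort("bits_per_sample must be 8 or 16", "io_error")
  }
  maxval <- 2^bits_per_sample - 1
  pages <- lapply(stack$slices, function(s) {
    s <- round(s)
    if (any(s > maxval)) {
      ccrit_abort(sprintf("intensities exceed %d; use a higher bit depth", maxval), "io_error")
    }
    s / maxval
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    ccrit_abort(sprintf("could not write '%s'", path), "io_error")
  }
  invisible(path)
}
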