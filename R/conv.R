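# 2-D convolution with symmetric-reflection borders, plus the two kernels the
# workflow needs. Kernels here are small (<= ~15 px), so a shift-and-add direct
# convolution over the padded image is both exact and fast enough; it avoids
# the wrap-around semantics of FFT filtering.

#' Reflect-pad a matrix
#' @noRd
pad_reflect <- function(x, top, bottom, left, right) {
  nr <- nrow(x); nc <- ncol(x)
  if (top >= nr || bottom >= nr || left >= nc || right >= nc) {
    ccrit_abort("kernel larger than image", "parameter_error")
  }
  ri <- c(rev(seq_len(top)), seq_len(nr), nr + 1 - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(nc), nc + 1 - seq_len(right))
  x[ri, ci, drop = FALSE]
}

#' 2-D convolution with reflective border handling
#'
#' Computes the discrete convolution `(image * kernel)` at every pixel, with
#' out-of-image samples taken by symmetric reflection. For even-sized kernels
#' the kernel origin is at index `floor(size/2) + 1`, so an impulse reproduces
#' the kernel without drift.
#'
#' @param image numeric matrix
#' @param kernel numeric matrix, both dimensions no larger than `image`
#' @return numeric matrix of the same shape as `image`
#' @export
#' @examples
#' convolve2(matrix(rnorm(25), 5, 5), matrix(1, 3, 3) / 9)
convolve2 <- function(image, kernel) {
  check_image(image)
  check_image(kernel, "kernel")
  kr <- nrow(kernel); kc <- ncol(kernel)
  # convolution flips the kernel relative to correlation
  kflip <- kernel[kr:1, kc:1, drop = FALSE]
  # origin of the flipped kernel, so that conv(impulse) == kernel
  oi <- kr - (kr %/% 2 + 1L) + 1L
  oj <- kc - (kc %/% 2 + 1L) + 1L
  top <- oi - 1L; bottom <- kr - oi
  left <- oj - 1L; right <- kc - oj
  p <- pad_reflect(image, top, bottom, left, right)
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kflip[a, b]
      if (w == 0) next
      out <- out + w * p[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
    }
  }
  out
}

#' Gaussian kernel, normalised to sum 1
#'
#' @param sigma standard deviation in pixels
#' @param size odd kernel size; defaults to covering +/- 3 sigma
#' @return numeric matrix
#' @export
gaussian_kernel <- function(sigma, size = NULL) {
  if (sigma <= 0) ccrit_abort("sigma must be > 0", "parameter_error")
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  half <- (size - 1) / 2
  ax <- seq(-half, half, length.out = size)
  g <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2))
  g / sum(g)
}

#' Negated Laplacian-of-Gaussian kernel
#'
#' Builds an `hsize` x `hsize` LoG kernel (grid offsets `-(hsize-1)/2` to
#' `(hsize-1)/2`), negated so that bright diffraction-limited spots produce
#' positive responses, and shifted to sum exactly to zero so a constant image
#' maps to a zero response.
#'
#' @param hsize kernel size in pixels (>= 3; 8 by default in the workflow)
#' @param sigma Gaussian sigma in pixels (0.8 by default in the workflow)
#' @return numeric matrix of shape `hsize` x `hsize`
#' @export
log_kernel <- function(hsize = 8L, sigma = 0.8) {
  if (hsize < 3L) ccrit_abort("hsize must be >= 3", "parameter_error")
  if (sigma <= 0) ccrit_abort("sigma must be > 0", "parameter_error")
  half <- (hsize - 1) / 2
  ax <- seq(-half, half, length.out = hsize)
  r2 <- outer(ax^2, ax^2, `+`)
  g <- exp(-r2 / (2 * sigma^2))
  g <- g / sum(g)
  h <- g * (r2 - 2 * sigma^2) / sigma^4
  h <- h - mean(h)   # exact zero sum
  -h                 # positive response on bright blobs
}
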