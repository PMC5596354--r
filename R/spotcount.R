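# The conventional automated spot-counting baseline: negated-LoG filtering,
# the spot-count-versus-threshold curve, automatic selection of a threshold
# from the noise-resilient plateau of that curve, and connected-component
# spot counting.

#' Laplacian-of-Gaussian filter an image
#'
#' Convolves with the negated zero-sum LoG kernel of [log_kernel()] (bright
#' diffraction-limited spots give positive responses), with symmetric
#' reflection at the borders. Responses smaller in magnitude than the
#' accumulated floating-point error bound of the convolution are snapped to
#' zero, so a constant image yields an exactly zero response.
#'
#' @param image 2-D numeric matrix
#' @param hsize kernel size in pixels (>= 3, default 8)
#' @param sigma Gaussian sigma in pixels (default 0.8)
#' @return numeric matrix of filter responses
#' @export
log_filter <- function(image, hsize = 8L, sigma = 0.8) {
  check_image(image)
  if (hsize > min(dim(image))) {
    ccrit_abort("hsize exceeds the image dimensions", "parameter_error")
  }
  out <- convolve2(image, log_kernel(hsize, sigma))
  tol <- hsize^2 * .Machine$double.eps * max(abs(image), 1)
  out[abs(out) < tol] <- 0
  out
}

#' Spot-count curve over a threshold grid
#'
#' For `n_bins` equally spaced thresholds spanning `(0, max(filtered)]`,
#' counts the connected components of the super-threshold (`>=`) binary
#' image. Each threshold is evaluated independently.
#'
#' @param filtered a LoG-filtered image with at least one positive value
#' @param n_bins number of thresholds (default 100)
#' @param connectivity component connectivity, 4 or 8
#' @return a tibble of class `ccrit_spot_curve` with columns `threshold` and
#'   `count`
#' @export
spot_curve <- function(filtered, n_bins = 100L, connectivity = 8L) {
  check_image(filtered)
  hi <- max(filtered)
  if (hi <= 0) {
    ccrit_abort("filtered image has no positive response", "degenerate_input")
  }
  th <- seq_len(n_bins) * hi / n_bins
  counts <- vapply(th, function(t) max(.cc_label(filtered >= t, as.integer(connectivity))),
                   integer(1))
  structure(
    tibble::tibble(threshold = th, count = counts),
    class = c("ccrit_spot_curve", class(tibble::tibble()))
  )
}

#' Longest runs of constant counts in a curve
#' @noRd
count_runs <- function(counts) {
  r <- rle(counts)
  tibble::tibble(
    value = r$values,
    length = r$lengths,
    start = cumsum(c(1L, head(r$lengths, -1L)))
  )
}

#' Select the plateau threshold of a spot-count curve
#'
#' Restricted to the sub-range with positive counts, the threshold at the
#' position of minimum absolute forward difference of the counts is returned.
#' When that minimum is zero (exactly equal consecutive counts), the first
#' position of the longest equal-count run is used, so a genuine plateau beats
#' an accidental early pair; remaining ties go to the lowest threshold.
#'
#' @param curve a `ccrit_spot_curve` (or tibble with `threshold`, `count`)
#' @param min_run_frac optionally require the chosen run of equal counts to
#'   span at least this fraction of the full grid; the default 0 imposes no
#'   plateau-quality requirement (see [run_spotcount()], which does)
#' @return the selected threshold (numeric scalar), with attributes `index`
#'   (position in the curve) and `run_length`
#' @export
select_plateau_threshold <- function(curve, min_run_frac = 0) {
  stopifnot(all(c("threshold", "count") %in% names(curve)))
  nz <- which(curve$count > 0L)
  if (length(nz) < 3L) {
    ccrit_abort("fewer than 3 thresholds with nonzero counts", "no_plateau")
  }
  # positive-count sub-range (contiguous by construction of the (0, max] grid)
  sub <- curve[nz, ]
  d <- abs(diff(sub$count))
  runs <- count_runs(sub$count)
  min_run <- ceiling(min_run_frac * nrow(curve))
  if (min(d) == 0L) {
    best <- runs[runs$length == max(runs$length), ][1L, ]  # earliest longest run
    if (best$length < min_run) {
      ccrit_abort("no sufficiently wide constant-count plateau", "no_plateau")
    }
    i <- best$start
    run_len <- best$length
  } else {
    if (min_run > 1L) {
      ccrit_abort("no sufficiently wide constant-count plateau", "no_plateau")
    }
    i <- which.min(d)  # first minimal |forward difference| = lowest threshold
    run_len <- 1L
  }
  structure(sub$threshold[i], index = nz[i], run_length = run_len)
}

#' Count spots above a threshold
#'
#' @param filtered LoG-filtered image
#' @param threshold positive reference intensity; pixels `>= threshold` are
#'   spot candidates
#' @param connectivity 4 or 8
#' @return list of class `spot_result`: `count`, `threshold`, `labels`
#'   (integer label matrix of the counted spots)
#' @export
count_spots <- function(filtered, threshold, connectivity = 8L) {
  check_image(filtered)
  if (threshold <= 0) ccrit_abort("threshold must be > 0", "parameter_error")
  labels <- .cc_label(filtered >= threshold, as.integer(connectivity))
  structure(
    list(count = max(labels), threshold = threshold, labels = labels),
    class = "spot_result"
  )
}

#' @export
print.spot_result <- function(x, ...) {
  cat(sprintf("<spot_result> %d spot(s) at threshold %.4g\n", x$count, x$threshold))
  invisible(x)
}

#' Run the conventional automated spot counter over a stack
#'
#' Per slice: LoG filter, spot-count curve, automatic plateau threshold,
#' component counting. A slice whose curve lacks a noise-resilient plateau
#' (no equal-count run spanning at least `plateau_min_frac` of the threshold
#' grid, or no positive filter response at all) reports 0 spots with a
#' warning, mirroring the behaviour of the method on transcript-free
#' specimens.
#'
#' @param stack the FISH-channel [image_stack]
#' @param config a [run_config()]
#' @return a tibble with one row per slice: `slice_index`, `count`,
#'   `threshold` (NA when no plateau), `plateau_run`; the per-slice
#'   [spot_curve()]s and [count_spots()] results are attached as attributes
#'   `curves` and `results`
#' @export
run_spotcount <- function(stack, config = run_config()) {
  stopifnot(inherits(stack, "image_stack"))
  curves <- vector("list", stack$n_slices)
  results <- vector("list", stack$n_slices)
  rows <- purrr::map(seq_len(stack$n_slices), function(k) {
    f <- log_filter(stack$slices[[k]], config$log_hsize, config$log_sigma)
    res <- tryCatch({
      cv <- spot_curve(f, config$n_bins, config$connectivity)
      curves[[k]] <<- cv
      t <- select_plateau_threshold(cv, min_run_frac = config$plateau_min_frac)
      sp <- count_spots(f, as.numeric(t), config$connectivity)
      results[[k]] <<- sp
      tibble::tibble(slice_index = k, count = sp$count,
                     threshold = as.numeric(t),
                     plateau_run = attr(t, "run_length"))
    },
    ccrit_no_plateau = function(e) {
      rlang::warn(sprintf("slice %d: no noise-resilient plateau; reporting 0 spots", k),
                  class = "ccrit_no_plateau_warning")
      tibble::tibble(slice_index = k, count = 0L, threshold = NA_real_,
                     plateau_run = 0L)
    },
    ccrit_degenerate_input = function(e) {
      rlang::warn(sprintf("slice %d: no positive LoG response; reporting 0 spots", k),
                  class = "ccrit_no_plateau_warning")
      tibble::tibble(slice_index = k, count = 0L, threshold = NA_real_,
                     plateau_run = 0L)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- curves
  attr(out, "results") <- results
  out
}
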