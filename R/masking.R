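# Mask construction from the maximum-intensity projection: the nucleus mask
# (central-bin threshold) and the background mask chosen by minimum
# area-weighted blob solidity, then refined by opening / erosion / infill.

#' Maximum-intensity projection of a stack
#'
#' @param stack an [image_stack]
#' @return numeric matrix; each pixel is the maximum of that pixel across all
#'   z slices
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  out <- stack$slices[[1]]
  for (s in stack$slices[-1]) out <- pmax(out, s)
  out
}

#' Candidate mask thresholds from equal-width intensity bins
#'
#' The image's intensity range `[min, max]` is split into `n_bins` equal-width
#' bins; each bin's upper edge `min + i * (max - min) / n_bins` is a candidate
#' threshold, so the grid is strictly increasing and ends at the image maximum.
#'
#' @param image numeric matrix with `max > min`
#' @param n_bins number of bins (>= 2)
#' @return numeric vector of `n_bins` thresholds
#' @export
#' @examples
#' candidate_thresholds(matrix(c(0, 100), 1), n_bins = 100)[50]  # 50
candidate_thresholds <- function(image, n_bins = 100L) {
  check_image(image)
  if (n_bins < 2L) ccrit_abort("n_bins must be >= 2", "parameter_error")
  lo <- min(image); hi <- max(image)
  if (hi <= lo) {
    ccrit_abort("image has a degenerate (constant) intensity range", "degenerate_range")
  }
  lo + seq_len(n_bins) * (hi - lo) / n_bins
}

#' Nucleus mask from the central-bin threshold
#'
#' Thresholds the MIP at the central candidate threshold (bin `n_bins / 2`,
#' i.e. the midpoint of the intensity range for the default 100 bins); pixels
#' strictly above it are nucleus.
#'
#' @param mip the maximum-intensity projection of the nuclear-stain stack
#' @inheritParams candidate_thresholds
#' @return logical matrix the same shape as `mip`
#' @export
nucleus_mask <- function(mip, n_bins = 100L) {
  th <- candidate_thresholds(mip, n_bins)
  central <- th[max(1L, n_bins %/% 2L)]
  mip > central
}

#' Background mask candidates scored by area-weighted solidity
#'
#' For each candidate threshold the below-threshold mask is labeled and scored
#' by the area-weighted mean blob solidity
#' `sum(area_b * solidity_b) / sum(area_b)`. Candidates with no blobs are
#' excluded. Pixel sets and masks are not retained (100 full-frame masks are
#' prohibitively large); [select_background_mask()] re-materialises the
#' winner's mask from its threshold.
#'
#' @inheritParams nucleus_mask
#' @param connectivity blob connectivity, 4 or 8
#' @return a tibble with columns `threshold`, `weighted_solidity`, `n_blobs`,
#'   `total_area`
#' @export
background_candidates <- function(mip, n_bins = 100L, connectivity = 8L) {
  th <- candidate_thresholds(mip, n_bins)
  rows <- purrr::map(th, function(t) {
    m <- mip < t
    if (!any(m)) return(NULL)
    ws <- weighted_solidity(m, connectivity)
    tibble::tibble(threshold = t, weighted_solidity = ws$weighted_solidity,
                   n_blobs = ws$n_blobs, total_area = ws$total_area)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    ccrit_abort("no candidate threshold produced a non-empty mask", "no_candidate")
  }
  out
}

#' Area-weighted mean blob solidity of a mask
#'
#' Blobs of one or two pixels are convex by construction (solidity 1), so only
#' larger components need a convex hull.
#'
#' @inheritParams background_candidates
#' @param mask logical matrix
#' @return list with `weighted_solidity`, `n_blobs`, `total_area`
#' @export
weighted_solidity <- function(mask, connectivity = 8L) {
  mask <- check_mask(mask)
  labels <- label_components(mask, connectivity)
  k <- max(labels)
  if (k == 0L) return(list(weighted_solidity = NA_real_, n_blobs = 0L, total_area = 0))
  areas <- tabulate(labels, nbins = k)
  sol <- rep(1, k)
  big <- which(areas > 2L)
  if (length(big) > 0L) {
    # hull vertices lie on the blob boundary, so only boundary pixels (those
    # with a 4-neighbour outside the mask, or on the frame edge) feed the hull
    nr <- nrow(mask); nc <- ncol(mask)
    interior <- matrix(FALSE, nr, nc)
    if (nr > 2L && nc > 2L) {
      core <- mask[2:(nr - 1L), 2:(nc - 1L)]
      interior[2:(nr - 1L), 2:(nc - 1L)] <-
        core &
        mask[1:(nr - 2L), 2:(nc - 1L)] & mask[3:nr, 2:(nc - 1L)] &
        mask[2:(nr - 1L), 1:(nc - 2L)] & mask[2:(nr - 1L), 3:nc]
    }
    idx <- which(mask & !interior)
    lab <- labels[idx]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    pix <- split(seq_along(lab), lab)
    for (nm in names(pix)) {
      b <- as.integer(nm)
      if (!(b %in% big)) next
      ii <- pix[[nm]]
      p <- cbind(rows[ii], cols[ii])
      # a blob filling its bounding box is convex
      bb <- (diff(range(p[, 1])) + 1L) * (diff(range(p[, 2])) + 1L)
      if (bb == areas[b]) next
      sol[b] <- areas[b] / convex_lattice_area(p)
    }
  }
  list(
    weighted_solidity = sum(areas * sol) / sum(areas),
    n_blobs = k,
    total_area = sum(areas)
  )
}

#' Select the background mask with minimum weighted solidity
#'
#' The lowest-threshold candidate attaining the minimum area-weighted solidity
#' wins; ragged, well-spread background blobs score low while compact bright
#' structures score high.
#'
#' @param candidates tibble from [background_candidates()]
#' @param mip the MIP the candidates were computed from
#' @inheritParams background_candidates
#' @return list with `threshold`, `weighted_solidity`, `mask` (logical matrix)
#'   and `blobs` (tibble from [label_blobs()])
#' @export
select_background_mask <- function(candidates, mip, connectivity = 8L) {
  if (nrow(candidates) == 0L) ccrit_abort("no candidates supplied", "no_candidate")
  i <- which.min(candidates$weighted_solidity)  # which.min takes the first = lowest threshold
  t <- candidates$threshold[i]
  mask <- mip < t
  list(
    threshold = t,
    weighted_solidity = candidates$weighted_solidity[i],
    mask = mask,
    blobs = label_blobs(mask, connectivity)
  )
}

#' Refine a background mask by opening, erosion and infill
#'
#' Three sequential stages: (1) morphological opening with a disk of radius
#' `open_disk_radius`, then removal of components smaller than
#' `open_min_area`; (2) erosion with a disk of radius `erosion_radius`;
#' (3) filling of interior holes of area at most `infill_max_hole`.
#'
#' @param mask logical matrix
#' @param config a [run_config()]
#' @return logical matrix
#' @export
refine_background_mask <- function(mask, config = run_config()) {
  mask <- check_mask(mask)
  if (!any(mask)) return(mask)
  m <- mask * 1
  m <- EBImage::opening(m, EBImage::makeBrush(2L * config$open_disk_radius + 1L, "disc"))
  m <- m == 1
  if (any(m)) {
    lab <- label_components(m, config$connectivity)
    if (max(lab) > 0L) {
      areas <- tabulate(lab, nbins = max(lab))
      small <- which(areas < config$open_min_area)
      if (length(small) > 0L) m[lab %in% small] <- FALSE
    }
  }
  if (any(m)) {
    m <- EBImage::erode(m * 1, EBImage::makeBrush(2L * config$erosion_radius + 1L, "disc")) == 1
  }
  if (any(m)) {
    m <- .cc_fill_holes(m, config$infill_max_hole, config$connectivity)
  }
  if (!any(m)) {
    rlang::warn("background mask is empty after refinement", class = "ccrit_empty_mask")
  }
  m
}

#' Build the nucleus and refined background masks for a stack
#'
#' Convenience wrapper running the full masking stage on a nuclear-stain
#' stack: MIP, nucleus mask, candidate scoring, selection and refinement.
#'
#' @param nucleus_stack the nuclear-stain [image_stack]
#' @inheritParams refine_background_mask
#' @return list of class `mask_pair`: `mip`, `nucleus_mask`,
#'   `background_mask` (refined), `background_threshold`, `candidates`
#' @export
build_masks <- function(nucleus_stack, config = run_config()) {
  mip <- max_intensity_projection(nucleus_stack)
  nmask <- nucleus_mask(mip, config$n_bins)
  cand <- background_candidates(mip, config$n_bins, config$connectivity)
  sel <- select_background_mask(cand, mip, config$connectivity)
  refined <- refine_background_mask(sel$mask, config)
  structure(
    list(
      mip = mip,
      nucleus_mask = nmask,
      background_mask = refined,
      background_mask_raw = sel$mask,
      background_threshold = sel$threshold,
      candidates = cand
    ),
    class = "mask_pair"
  )
}

#' @export
print.mask_pair <- function(x, ...) {
  cat(sprintf(
    "<mask_pair> %d x %d px; nucleus px: %d; background px (refined): %d; background threshold: %.4g\n",
    nrow(x$mip), ncol(x$mip), sum(x$nucleus_mask), sum(x$background_mask),
    x$background_threshold
  ))
  invisible(x)
}
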