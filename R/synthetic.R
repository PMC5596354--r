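# Ground-truthed synthetic dual-channel stacks emulating whole-mount retina
# specimens: radially clustered nuclei (up to 7 per ommatidium), PSF-blurred
# diffraction-limited transcript spots confined to a subset of nuclei, uniform
# background noise with optional depth-dependent growth, and integer
# quantisation as in real TIFF exports. Everything is reproducible under an
# explicit seed, and every planted quantity is returned so downstream metrics
# have exact ground truth.

#' Synthetic layout parameters
#'
#' Defaults describe the package's reference specimen: a 512 x 512 frame, 10
#' slices, 9 ommatidia on a jittered 3 x 3 grid of pitch 120 px (three ring
#' radii), 7 nuclei of radius ~14.5 px on a 40 px ring. The nucleus ring is
#' deliberately tight: gaps between neighbouring nuclei stay below the
#' 11 px opening diameter used in mask refinement, so each ommatidium's dark
#' centre seals into one interior background blob - the anchor geometry of
#' the real tissue.
#'
#' @param frame frame side in pixels
#' @param n_slices number of z slices
#' @param n_ommatidia number of ommatidia (laid out on a near-square grid)
#' @param nuclei_per_ommatidium nuclei per cluster (<= 7)
#' @param ring_radius nucleus ring radius in pixels
#' @param spacing grid pitch between ommatidium centres (must exceed
#'   `2 * ring_radius`)
#' @param nucleus_radius nominal nucleus disc radius in pixels
#' @param anchor_jitter uniform jitter (+/- px) of ommatidium centres
#' @param angle_jitter uniform jitter (+/- degrees) of nucleus ring angles
#' @param radius_sd relative jitter of the ring radius
#' @param base_spots planted transcript spots per expressing cell at relative
#'   level 1
#' @param spot_amplitude peak spot amplitude (intensity units)
#' @param psf_sigma in-plane PSF sigma of rendered spots (px)
#' @param nucleus_amplitude nuclear-stain disc amplitude
#' @param nucleus_background flat nuclear-channel background offset (detector
#'   offset plus tissue autofluorescence)
#' @param fish_noise_mean,fish_noise_sd uniform FISH background noise
#' @param depth_decay per-slice relative growth of the FISH noise sd
#'   (signal-to-noise falls with imaging depth)
#' @param nucleus_noise_sd per-pixel noise sd of the nuclear channel (kept
#'   below the quantisation step: the nuclear stain is imaged at high SNR and
#'   masking robustness to nuclear-channel noise is not a validation target)
#' @return a list of layout parameters
#' @export
synth_params <- function(frame = 512L, n_slices = 10L, n_ommatidia = 9L,
                         nuclei_per_ommatidium = 7L, ring_radius = 40,
                         spacing = 120, nucleus_radius = 14.5,
                         anchor_jitter = 5, angle_jitter = 1.5,
                         radius_sd = 0.02, base_spots = 40L,
                         spot_amplitude = 150, psf_sigma = 1.6,
                         nucleus_amplitude = 180, nucleus_background = 20,
                         fish_noise_mean = 6,
                         fish_noise_sd = 1.2, depth_decay = 0.03,
                         nucleus_noise_sd = 0.15) {
  p <- as.list(environment())
  if (p$spacing <= 2 * p$ring_radius) {
    ccrit_abort("spacing must exceed 2 * ring_radius", "geometry_error")
  }
  if (p$nuclei_per_ommatidium > 7L) {
    ccrit_abort("at most 7 nuclei per ommatidium", "geometry_error")
  }
  p
}

#' Generate a ground-truth layout of ommatidia and nuclei
#'
#' Ommatidium anchors sit on a jittered near-square grid; nuclei at jittered
#' equal angles on a ring about each anchor. Identical seed and parameters
#' give an identical layout.
#'
#' @param params a [synth_params()] list
#' @param seed integer seed
#' @return a list of class `ccrit_truth`: `params`, `seed`, `ommatidia`
#'   (tibble: `ommatidium`, `center_row`, `center_col`), `nuclei` (tibble:
#'   `ommatidium`, `cell_index`, `center_row`, `center_col`, `radius`,
#'   `expressing`), and empty `spots`
#' @export
generate_layout <- function(params = synth_params(), seed = 1L) {
  p <- params
  withr::with_seed(as.integer(seed), {
    side <- ceiling(sqrt(p$n_ommatidia))
    gpos <- (seq_len(side) - (side + 1) / 2) * p$spacing + (p$frame + 1) / 2
    grid <- expand.grid(row = gpos, col = gpos)[seq_len(p$n_ommatidia), ]
    extent <- p$ring_radius * (1 + 3 * p$radius_sd) + p$nucleus_radius + 2
    if (any(grid < extent + p$anchor_jitter) ||
        any(grid > p$frame - extent - p$anchor_jitter)) {
      ccrit_abort("layout does not fit the frame", "geometry_error")
    }
    n <- p$n_ommatidia
    centers <- cbind(
      grid$row + stats::runif(n, -p$anchor_jitter, p$anchor_jitter),
      grid$col + stats::runif(n, -p$anchor_jitter, p$anchor_jitter)
    )
    nuc <- purrr::map(seq_len(n), function(o) {
      k <- p$nuclei_per_ommatidium
      base <- stats::runif(1, 0, 2 * pi)
      ang <- base + 2 * pi * (seq_len(k) - 1L) / k +
        stats::runif(k, -p$angle_jitter, p$angle_jitter) * pi / 180
      rr <- p$ring_radius * (1 + stats::rnorm(k, 0, p$radius_sd))
      tibble::tibble(
        ommatidium = o,
        cell_index = seq_len(k),
        center_row = centers[o, 1] - rr * sin(ang),
        center_col = centers[o, 2] + rr * cos(ang),
        radius = p$nucleus_radius + stats::runif(k, -0.5, 0.5),
        # one cell per cluster does not express (the R7 analog)
        expressing = seq_len(k) != k
      )
    })
    structure(
      list(
        params = p,
        seed = as.integer(seed),
        ommatidia = tibble::tibble(
          ommatidium = seq_len(n),
          center_row = centers[, 1],
          center_col = centers[, 2]
        ),
        nuclei = dplyr::bind_rows(nuc),
        spots = tibble::tibble(
          ommatidium = integer(), cell_index = integer(), slice = integer(),
          row = numeric(), col = numeric(), amplitude = numeric()
        ),
        spots_per_cell = 0L
      ),
      class = "ccrit_truth"
    )
  })
}

#' Plant transcript spots in the expressing cells of a layout
#'
#' Each expressing cell receives `spots_per_cell` spots, uniformly placed
#' inside its nucleus disc (2 px margin) on a uniformly chosen slice, with 10
#' percent amplitude jitter. Non-expressing cells receive none.
#'
#' @param truth a `ccrit_truth` from [generate_layout()]
#' @param spots_per_cell planted spots per expressing cell
#' @param seed integer seed
#' @return the layout with its `spots` tibble populated
#' @export
plant_spots <- function(truth, spots_per_cell, seed = 1L) {
  p <- truth$params
  withr::with_seed(as.integer(seed), {
    nuc <- truth$nuclei[truth$nuclei$expressing, ]
    spots <- purrr::map(seq_len(nrow(nuc)), function(i) {
      k <- as.integer(spots_per_cell)
      if (k == 0L) return(NULL)
      r <- (nuc$radius[i] - 2) * sqrt(stats::runif(k))
      a <- stats::runif(k, 0, 2 * pi)
      tibble::tibble(
        ommatidium = nuc$ommatidium[i],
        cell_index = nuc$cell_index[i],
        slice = sample.int(p$n_slices, k, replace = TRUE),
        row = nuc$center_row[i] + r * sin(a),
        col = nuc$center_col[i] + r * cos(a),
        amplitude = p$spot_amplitude * stats::runif(k, 0.9, 1.1)
      )
    })
    truth$spots <- dplyr::bind_rows(spots)
    truth$spots_per_cell <- as.integer(spots_per_cell)
    truth
  })
}

#' Render a soft-edged disc onto an accumulator image
#' @noRd
render_disc <- function(img, row, col, radius, amplitude, edge = 1.5) {
  n <- nrow(img)
  lo_r <- max(1L, floor(row - radius - 4 * edge)); hi_r <- min(n, ceiling(row + radius + 4 * edge))
  lo_c <- max(1L, floor(col - radius - 4 * edge)); hi_c <- min(ncol(img), ceiling(col + radius + 4 * edge))
  rr <- lo_r:hi_r; cc <- lo_c:hi_c
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, `+`))
  img[rr, cc] <- img[rr, cc] + amplitude / (1 + exp((d - radius) / edge))
  img
}

#' Render an isotropic Gaussian spot onto an accumulator image
#' @noRd
render_spot <- function(img, row, col, sigma, amplitude) {
  n <- nrow(img)
  ext <- ceiling(5 * sigma)
  lo_r <- max(1L, floor(row - ext)); hi_r <- min(n, ceiling(row + ext))
  lo_c <- max(1L, floor(col - ext)); hi_c <- min(ncol(img), ceiling(col + ext))
  rr <- lo_r:hi_r; cc <- lo_c:hi_c
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Render the dual-channel stacks for a layout
#'
#' The nuclear channel is the sum of soft-edged discs at the nuclei, constant
#' across slices, over a smooth linear illumination ramp plus per-slice pixel
#' noise. The FISH channel is the sum of PSF-blurred Gaussian spots, each on
#' its planted slice, over uniform background noise whose sd grows with slice
#' index by `depth_decay`. Both channels are floored at zero and quantised to
#' integers, as in real acquisitions.
#'
#' @param truth a `ccrit_truth`, usually after [plant_spots()]
#' @param seed integer seed (noise only; geometry lives in the layout)
#' @return list with `nucleus` and `fish` [image_stack]s and `truth`
#' @export
render_stacks <- function(truth, seed = 1L) {
  p <- truth$params
  withr::with_seed(as.integer(seed), {
    n <- p$frame
    discs <- matrix(0, n, n)
    for (i in seq_len(nrow(truth$nuclei))) {
      discs <- render_disc(discs, truth$nuclei$center_row[i],
                           truth$nuclei$center_col[i],
                           truth$nuclei$radius[i], p$nucleus_amplitude)
    }
    spot_imgs <- vector("list", p$n_slices)
    for (k in seq_len(p$n_slices)) spot_imgs[[k]] <- matrix(0, n, n)
    sp <- truth$spots
    if (nrow(sp) > 0L) {
      for (i in seq_len(nrow(sp))) {
        k <- sp$slice[i]
        spot_imgs[[k]] <- render_spot(spot_imgs[[k]], sp$row[i], sp$col[i],
                                      p$psf_sigma, sp$amplitude[i])
      }
    }
    nucleus <- vector("list", p$n_slices)
    fish <- vector("list", p$n_slices)
    for (k in seq_len(p$n_slices)) {
      nucleus[[k]] <- pmax(round(discs + p$nucleus_background +
                                   matrix(stats::rnorm(n * n, 0, p$nucleus_noise_sd), n, n)), 0)
      sdk <- p$fish_noise_sd * (1 + p$depth_decay * (k - 1L))
      fish[[k]] <- pmax(round(spot_imgs[[k]] +
                                matrix(stats::rnorm(n * n, p$fish_noise_mean, sdk), n, n)), 0)
    }
    list(
      nucleus = image_stack(nucleus, "NUCLEUS"),
      fish = image_stack(fish, "FISH"),
      truth = truth
    )
  })
}

#' Generate one complete synthetic specimen
#'
#' Layout + planted spots + rendered stacks in one call. `level` scales the
#' planted spot count: `spots_per_cell = round(level * base_spots)`.
#'
#' @param level relative expression level in `[0, 1]`
#' @param params a [synth_params()] list
#' @param seed integer seed
#' @return list with `nucleus`, `fish`, `truth`
#' @export
synth_specimen <- function(level = 1, params = synth_params(), seed = 1L) {
  if (level < 0 || level > 1) ccrit_abort("level must be in [0, 1]", "parameter_error")
  truth <- generate_layout(params, seed = seed)
  truth <- plant_spots(truth, round(level * params$base_spots), seed = seed + 1L)
  render_stacks(truth, seed = seed + 2L)
}

#' Generate a genotype series of synthetic specimens
#'
#' One specimen per relative expression level, emulating a wild-type /
#' heterozygote / null series (levels 1, ~0.7, 0): each expressing cell gets
#' `round(level * base_spots)` spots; the non-expressing cell of every
#' cluster gets none.
#'
#' @param levels numeric vector of relative levels in `[0, 1]`
#' @param replicates specimens per level
#' @param params a [synth_params()] list
#' @param seed integer base seed; each specimen uses a distinct derived seed
#' @return a tibble with columns `level`, `replicate`, `spots_per_cell`,
#'   `specimen` (list of rendered specimens)
#' @export
genotype_series <- function(levels = c(1, 0.7, 0), replicates = 1L,
                            params = synth_params(), seed = 1L) {
  if (any(levels < 0 | levels > 1)) ccrit_abort("levels must be in [0, 1]", "parameter_error")
  grid <- expand.grid(replicate = seq_len(replicates), level = levels)
  specimens <- purrr::map(seq_len(nrow(grid)), function(i) {
    synth_specimen(grid$level[i], params,
                   seed = as.integer(seed) + 101L * i)
  })
  tibble::tibble(
    level = grid$level,
    replicate = grid$replicate,
    spots_per_cell = vapply(specimens, function(s) s$truth$spots_per_cell, integer(1)),
    specimen = specimens
  )
}

#' Generate a sparse high-SNR spot field for the spot-counting baseline
#'
#' Plants `n_spots` well-separated spots per slice (jittered grid positions,
#' minimum separation several PSF widths) on a uniform noise background - the
#' regime in which conventional LoG counting works well.
#'
#' @param n_spots spots per slice
#' @param frame frame side (px)
#' @param n_slices slices
#' @param amplitude spot amplitude
#' @param psf_sigma spot sigma (px)
#' @param noise_mean,noise_sd background noise
#' @param seed integer seed
#' @return list with `fish` ([image_stack]) and `spots` tibble
#'   (`slice`, `row`, `col`, `amplitude`)
#' @export
synth_spot_field <- function(n_spots = 20L, frame = 256L, n_slices = 10L,
                             amplitude = 150, psf_sigma = 1.6,
                             noise_mean = 6, noise_sd = 1.2, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    side <- ceiling(sqrt(n_spots))
    pitch <- (frame - 20) / side
    if (pitch < 8 * psf_sigma) {
      ccrit_abort("frame too small for well-separated spots", "geometry_error")
    }
    slices <- vector("list", n_slices)
    spots <- vector("list", n_slices)
    for (k in seq_len(n_slices)) {
      g <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n_spots), ]
      row <- 10 + (g$i - 0.5) * pitch + stats::runif(n_spots, -pitch / 6, pitch / 6)
      col <- 10 + (g$j - 0.5) * pitch + stats::runif(n_spots, -pitch / 6, pitch / 6)
      amp <- amplitude * stats::runif(n_spots, 0.9, 1.1)
      img <- matrix(0, frame, frame)
      for (s in seq_len(n_spots)) {
        img <- render_spot(img, row[s], col[s], psf_sigma, amp[s])
      }
      img <- img + matrix(stats::rnorm(frame * frame, noise_mean, noise_sd), frame, frame)
      slices[[k]] <- pmax(round(img), 0)
      spots[[k]] <- tibble::tibble(slice = k, row = row, col = col, amplitude = amp)
    }
    list(fish = image_stack(slices, "FISH"), spots = dplyr::bind_rows(spots))
  })
}

#' @export
print.ccrit_truth <- function(x, ...) {
  cat(sprintf(
    "<ccrit_truth> %d ommatidia x %d nuclei, %d planted spot(s) (%d per expressing cell), seed %d\n",
    nrow(x$ommatidia), x$params$nuclei_per_ommatidium, nrow(x$spots),
    x$spots_per_cell, x$seed
  ))
  invisible(x)
}

#' Write ground-truth tables next to rendered stacks
#'
#' Emits `nuclei.csv` and `spots.csv` so downstream metrics are computable
#' without re-generation.
#'
#' @param truth a `ccrit_truth`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$nuclei, file.path(dir, "nuclei.csv"), row.names = FALSE)
  utils::write.csv(truth$spots, file.path(dir, "spots.csv"), row.names = FALSE)
  invisible(dir)
}
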