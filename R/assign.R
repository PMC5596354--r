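# Grouping nucleus blobs into ommatidia. Each refined background blob is an
# anchor; sorted anchor-to-nucleus centroid distances show a near/far gap at
# the ommatidium boundary, found as a dominant peak in the forward
# differences. Cells are then numbered 1..k counter-clockwise.

#' Sorted centroid distance profile
#'
#' Euclidean distances from an anchor to every nucleus centroid, sorted
#' ascending, stable on ties (lower nucleus index first).
#'
#' @param anchor numeric (row, col) of the anchor (background blob) centroid
#' @param nucleus_centroids 2-column matrix of nucleus (row, col) centroids
#' @return a tibble with columns `distance`, `nucleus` (index into the input)
#' @export
#' @examples
#' distance_profile(c(0, 0), rbind(c(3, 4), c(6, 8)))$distance  # 5, 10
distance_profile <- function(anchor, nucleus_centroids) {
  m <- as.matrix(nucleus_centroids)
  if (nrow(m) < 1L) ccrit_abort("need at least one nucleus centroid", "assignment_error")
  d <- sqrt((m[, 1] - anchor[1])^2 + (m[, 2] - anchor[2])^2)
  o <- order(d, seq_along(d))
  tibble::tibble(distance = d[o], nucleus = o)
}

#' Near/far cutoff from the dominant gap in sorted distances
#'
#' Forward differences of the ascending distances are scanned for the first
#' positive local maximum exceeding `gap_factor` times the median of the
#' remaining differences (so a single dominant gap qualifies even in short
#' profiles). The returned cutoff is the number of "near" nuclei, capped at
#' `max_near`; when no gap qualifies, `min(length, max_near)` is returned.
#'
#' @param sorted_distances ascending numeric vector, length >= 2
#' @param gap_factor dominance factor (default 3)
#' @param max_near cap on the near count (default 7: R8 nuclei are not
#'   visible in the imaged planes)
#' @return integer cutoff
#' @export
near_cutoff <- function(sorted_distances, gap_factor = 3, max_near = 7L) {
  n <- length(sorted_distances)
  if (n < 2L) ccrit_abort("need at least two distances", "assignment_error")
  if (is.unsorted(sorted_distances)) {
    ccrit_abort("distances must be sorted ascending", "assignment_error")
  }
  d <- diff(sorted_distances)
  nd <- length(d)
  for (i in seq_len(nd)) {
    if (d[i] <= 0) next
    left <- if (i > 1L) d[i - 1L] else -Inf
    right <- if (i < nd) d[i + 1L] else -Inf
    if (d[i] < left || d[i] < right) next  # not a local maximum
    others <- d[-i]
    ref <- if (length(others) == 0L) 0 else median(others)
    if (d[i] > gap_factor * ref) {
      return(min(i, as.integer(max_near)))
    }
  }
  min(n, as.integer(max_near))
}

#' Number cells counter-clockwise about an anchor
#'
#' Angles are measured with image "north" up: `atan2(-(row - row0), col -
#' col0)`, so increasing angle is counter-clockwise on screen. Numbering
#' starts at the cell with the smallest non-negative angle (image east) and
#' proceeds counter-clockwise.
#'
#' @param anchor numeric (row, col) anchor centroid
#' @param centroids 2-column matrix of cell (row, col) centroids, 1..7 rows
#' @return integer vector: for each input cell its number 1..k
#' @export
number_cells_ccw <- function(anchor, centroids) {
  m <- as.matrix(centroids)
  k <- nrow(m)
  if (k < 1L) ccrit_abort("no cells to number", "assignment_error")
  if (anyDuplicated(m) > 0L) {
    ccrit_abort("two cells share a centroid", "degenerate_geometry")
  }
  ang <- atan2(-(m[, 1] - anchor[1]), m[, 2] - anchor[2])
  ang <- ang %% (2 * pi)  # [0, 2pi): start = smallest non-negative angle
  order(order(ang, seq_len(k)))
}

#' Assign nucleus blobs to ommatidia
#'
#' Anchors (background blobs) are processed in row-major order of centroid and
#' labeled A, B, C, ... Each anchor claims its near set per [near_cutoff()];
#' a nucleus claimed by several anchors goes to the nearest (ties to the
#' earlier label); unclaimed nuclei are excluded and reported in the
#' `unassigned` attribute. Cells within an ommatidium are numbered
#' counter-clockwise.
#'
#' @param background_blobs tibble from [label_blobs()] for the refined
#'   background mask (anchors)
#' @param nucleus_blobs tibble from [label_blobs()] for the nucleus mask
#' @param gap_factor see [near_cutoff()]
#' @param max_cells maximum cells per ommatidium (default 7)
#' @return a tibble of class `cell_map` with columns `ommatidium_label`,
#'   `anchor_row`, `anchor_col`, `cell_number`, `nucleus_label`,
#'   `centroid_row`, `centroid_col`, `area`, `pixels`; attribute `unassigned`
#'   lists excluded nucleus labels
#' @export
assign_ommatidia <- function(background_blobs, nucleus_blobs,
                             gap_factor = 3, max_cells = 7L) {
  if (nrow(background_blobs) == 0L) {
    ccrit_abort("no background blobs to anchor ommatidia", "assignment_error")
  }
  if (nrow(nucleus_blobs) == 0L) {
    ccrit_abort("no nucleus blobs to assign", "assignment_error")
  }
  anchors <- background_blobs[order(background_blobs$centroid_row,
                                    background_blobs$centroid_col), ]
  anchors$ommatidium_label <- make_letter_labels(nrow(anchors))
  centroids <- cbind(nucleus_blobs$centroid_row, nucleus_blobs$centroid_col)

  # each anchor's claim: near set with distances
  claims <- purrr::map(seq_len(nrow(anchors)), function(a) {
    prof <- distance_profile(c(anchors$centroid_row[a], anchors$centroid_col[a]),
                             centroids)
    k <- if (nrow(prof) == 1L) 1L else near_cutoff(prof$distance, gap_factor, max_cells)
    tibble::tibble(anchor = a, nucleus = prof$nucleus[seq_len(k)],
                   distance = prof$distance[seq_len(k)])
  })
  claims <- dplyr::bind_rows(claims)
  # competing claims: nearest anchor wins, ties to the earlier label
  claims <- claims[order(claims$nucleus, claims$distance, claims$anchor), ]
  winner <- claims[!duplicated(claims$nucleus), ]

  rows <- purrr::map(seq_len(nrow(anchors)), function(a) {
    mine <- winner[winner$anchor == a, ]
    if (nrow(mine) == 0L) return(NULL)
    nb <- nucleus_blobs[mine$nucleus, ]
    num <- number_cells_ccw(c(anchors$centroid_row[a], anchors$centroid_col[a]),
                            cbind(nb$centroid_row, nb$centroid_col))
    tibble::tibble(
      ommatidium_label = anchors$ommatidium_label[a],
      anchor_row = anchors$centroid_row[a],
      anchor_col = anchors$centroid_col[a],
      cell_number = num,
      nucleus_label = nb$label,
      centroid_row = nb$centroid_row,
      centroid_col = nb$centroid_col,
      area = nb$area,
      pixels = nb$pixels
    )[order(num), ]
  })
  out <- dplyr::bind_rows(rows)
  unassigned <- setdiff(nucleus_blobs$label, out$nucleus_label)
  if (length(unassigned) > 0L) {
    ccrit_log(sprintf("%d nucleus blob(s) not claimed by any ommatidium: %s",
                      length(unassigned), paste(unassigned, collapse = ", ")))
  }
  attr(out, "unassigned") <- unassigned
  class(out) <- c("cell_map", class(out))
  out
}

#' Letter labels A, B, ..., Z, AA, AB, ...
#' @noRd
make_letter_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}
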