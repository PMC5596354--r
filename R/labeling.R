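# Connected components and blob geometry. Labeling is a compiled two-pass
# union-find (4- or 8-connectivity); blob solidity uses the exact count of
# pixel centres inside-or-on the convex hull of the component's pixel centres,
# which keeps solidity <= 1 exactly and equal to 1 for rasterised convex
# shapes (squares, rectangles, straight lines).

#' Label connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 4 or 8
#' @return integer matrix of component labels (0 = background), numbered in
#'   deterministic first-touch order
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- check_mask(mask)
  if (!connectivity %in% c(4L, 8L)) {
    ccrit_abort("connectivity must be 4 or 8", "parameter_error")
  }
  .cc_label(mask, as.integer(connectivity))
}

#' Number of lattice points inside-or-on the convex hull of integer points
#'
#' Scanline over hull rows; the hull of a convex polygon meets each row in a
#' single interval, whose integer x positions are counted with a small
#' tolerance so boundary points are included.
#'
#' @param pts 2-column matrix of integer (row, col) coordinates
#' @return lattice-point count (>= nrow of unique pts)
#' @keywords internal
convex_lattice_area <- function(pts) {
  pts <- pts[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n <= 2L) return(collinear_count(unique(pts)))
  hull_idx <- grDevices::chull(pts[, 2], pts[, 1])  # (x = col, y = row)
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) <= 2L) return(collinear_count(unique(pts)))
  tol <- 1e-9
  hy <- hull[, 1]; hx <- hull[, 2]
  m <- length(hy)
  nxt <- c(2:m, 1)
  total <- 0
  for (y in seq(min(hy), max(hy))) {
    xmin <- Inf; xmax <- -Inf
    for (e in seq_len(m)) {
      y1 <- hy[e]; y2 <- hy[nxt[e]]
      x1 <- hx[e]; x2 <- hx[nxt[e]]
      lo <- min(y1, y2); hi <- max(y1, y2)
      if (y < lo - tol || y > hi + tol) next
      if (abs(y2 - y1) < tol) {          # horizontal edge on this row
        xmin <- min(xmin, x1, x2); xmax <- max(xmax, x1, x2)
      } else {
        x <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        xmin <- min(xmin, x); xmax <- max(xmax, x)
      }
    }
    if (is.finite(xmin)) {
      total <- total + max(0L, floor(xmax + tol) - ceiling(xmin - tol) + 1L)
    }
  }
  total
}

#' Lattice points on the segment spanned by collinear integer points
#' @noRd
collinear_count <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(max(n, 1L))
  # extreme points along the common direction
  o <- order(pts[, 1], pts[, 2])
  p1 <- pts[o[1], ]; p2 <- pts[o[n], ]
  d <- abs(p2 - p1)
  if (all(d == 0)) return(1L)
  as.integer(gcd2(d[1], d[2]) + 1L)
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Extract blobs (connected components) with geometry
#'
#' One row per connected component, with its area, the lattice-raster area of
#' its convex hull, solidity (area / convex area), centroid, and the pixel
#' coordinate set as a list column.
#'
#' @inheritParams label_components
#' @param labels optionally, a precomputed label matrix from
#'   [label_components()] (then `mask` is ignored)
#' @return a tibble with columns `label`, `area`, `convex_area`, `solidity`,
#'   `centroid_row`, `centroid_col`, `touches_border`, `pixels`
#' @export
#' @examples
#' m <- matrix(0, 6, 6); m[2:4, 2:4] <- 1
#' label_blobs(m)$solidity  # filled square: 1
label_blobs <- function(mask, connectivity = 8L, labels = NULL) {
  if (is.null(labels)) {
    labels <- label_components(mask, connectivity)
  }
  k <- max(labels)
  if (k == 0L) {
    return(tibble::tibble(
      label = integer(), area = numeric(), convex_area = numeric(),
      solidity = numeric(), centroid_row = numeric(), centroid_col = numeric(),
      touches_border = logical(), pixels = list()
    ))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  ord <- order(lab, idx)
  lab <- lab[ord]; rows <- rows[ord]; cols <- cols[ord]
  splits <- split(seq_along(lab), lab)
  nr <- nrow(labels); nc <- ncol(labels)
  res <- purrr::map(unname(splits), function(ii) {
    p <- cbind(row = rows[ii], col = cols[ii])
    ca <- convex_lattice_area(p)
    list(
      area = nrow(p),
      convex_area = ca,
      solidity = nrow(p) / ca,
      centroid_row = mean(p[, 1]),
      centroid_col = mean(p[, 2]),
      touches_border = any(p[, 1] == 1L | p[, 1] == nr |
                             p[, 2] == 1L | p[, 2] == nc),
      pixels = p
    )
  })
  tibble::tibble(
    label = as.integer(names(splits)),
    area = purrr::map_dbl(res, "area"),
    convex_area = purrr::map_dbl(res, "convex_area"),
    solidity = purrr::map_dbl(res, "solidity"),
    centroid_row = purrr::map_dbl(res, "centroid_row"),
    centroid_col = purrr::map_dbl(res, "centroid_col"),
    touches_border = purrr::map_lgl(res, "touches_border"),
    pixels = purrr::map(res, "pixels")
  )
}
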