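# Independent oracles used across the suite. These deliberately share no code
# with the package: labeling by breadth-first flood fill, hull rasterisation
# by point-in-polygon testing, statistics by explicit loops.

# Breadth-first flood-fill connected-component labeling.
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] > 0L) next
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue) > 0L) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (q in seq_len(nrow(nb))) {
          r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- k
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Lattice points inside-or-on the convex hull of integer points, by direct
# point-in-polygon testing over the bounding box (pracma::inpolygon).
hull_lattice_oracle <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) <= 2L || all_collinear(pts)) {
    return(segment_lattice_oracle(pts))
  }
  h <- grDevices::chull(pts[, 2], pts[, 1])
  xv <- pts[h, 2]; yv <- pts[h, 1]
  grid <- expand.grid(
    row = seq(min(pts[, 1]), max(pts[, 1])),
    col = seq(min(pts[, 2]), max(pts[, 2]))
  )
  sum(pracma::inpolygon(grid$col, grid$row, xv, yv, boundary = TRUE))
}

all_collinear <- function(pts) {
  if (nrow(pts) <= 2L) return(TRUE)
  v <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cross <- v[1, 1] * v[, 2] - v[1, 2] * v[, 1]
  all(abs(cross) < 1e-9)
}

# Lattice points on the extreme segment of a collinear integer point set.
segment_lattice_oracle <- function(pts) {
  if (nrow(pts) == 1L) return(1L)
  o <- order(pts[, 1], pts[, 2])
  p1 <- pts[o[1], ]; p2 <- pts[o[nrow(pts)], ]
  grid <- expand.grid(
    row = seq(min(pts[, 1]), max(pts[, 1])),
    col = seq(min(pts[, 2]), max(pts[, 2]))
  )
  on_seg <- vapply(seq_len(nrow(grid)), function(i) {
    p <- c(grid$row[i], grid$col[i])
    cross <- (p2[1] - p1[1]) * (p[2] - p1[2]) - (p2[2] - p1[2]) * (p[1] - p1[1])
    abs(cross) < 1e-9 &&
      p[1] >= min(p1[1], p2[1]) - 1e-9 && p[1] <= max(p1[1], p2[1]) + 1e-9 &&
      p[2] >= min(p1[2], p2[2]) - 1e-9 && p[2] <= max(p1[2], p2[2]) + 1e-9
  }, logical(1))
  sum(on_seg)
}

# Random connected blob grown by random walk from a seed pixel.
random_blob <- function(n_pixels, grid = 20L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, grid, grid)
    p <- c(grid %/% 2L, grid %/% 2L)
    m[p[1], p[2]] <- TRUE
    count <- 1L
    guard <- 0L
    while (count < n_pixels && guard < 50L * n_pixels) {
      guard <- guard + 1L
      step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      q <- pmin(pmax(p + step, 1L), grid)
      if (!m[q[1], q[2]]) {
        m[q[1], q[2]] <- TRUE
        count <- count + 1L
      }
      p <- q
    }
    m
  })
}

# Random sparse binary image.
random_binary <- function(nr, nc, density, seed) {
  withr::with_seed(seed, matrix(stats::runif(nr * nc) < density, nr, nc))
}

# Small synthetic parameter set for fast pipeline tests: 4 ommatidia in a
# 256 px frame, same local geometry as the default specimen.
small_params <- function(...) {
  synth_params(frame = 256L, n_slices = 6L, n_ommatidia = 4L, ...)
}
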