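# Moore-neighbor boundary tracing with Jacob's stopping criterion: walk the
# 8-neighborhood clockwise around the outer contour of a connected component,
# terminating when the start pixel is re-entered from its original entry
# direction. The classic companion of blob labeling for nuclei outlines.

# clockwise Moore neighborhood starting at west, in (drow, dcol):
# W, NW, N, NE, E, SE, S, SW
.moore <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                 ncol = 2, byrow = TRUE)

#' Trace the outer boundary of a blob
#'
#' @param blob either one row of a [label_blobs()] tibble, or a 2-column
#'   (row, col) matrix of pixel coordinates of one 8-connected component
#' @return an integer matrix of (row, col) boundary coordinates, clockwise,
#'   starting at the topmost-leftmost pixel; a single-pixel blob yields a
#'   single row
#' @export
#' @examples
#' sq <- as.matrix(expand.grid(row = 2:4, col = 2:4))
#' nrow(trace_boundary(sq))  # 8 boundary pixels of a 3x3 square
trace_boundary <- function(blob) {
  pts <- blob_pixels(blob)
  if (nrow(pts) == 0L) ccrit_abort("blob is empty", "degenerate_geometry")
  if (nrow(pts) == 1L) return(pts)
  # embed in a local mask with a 1-px margin on every side
  r0 <- min(pts[, 1]) - 2L; c0 <- min(pts[, 2]) - 2L
  nr <- max(pts[, 1]) - r0 + 2L; nc <- max(pts[, 2]) - c0 + 2L
  m <- matrix(FALSE, nr, nc)
  loc <- cbind(pts[, 1] - r0, pts[, 2] - c0)
  m[loc] <- TRUE
  # start: topmost, then leftmost foreground pixel; entered moving east, so
  # the backtrack (previous exterior) pixel is its west neighbor
  top <- min(loc[, 1])
  start <- c(top, min(loc[loc[, 1] == top, 2]))
  start_dir <- 1L  # index into .moore of the backtrack direction (west)
  path <- list()
  cur <- start
  dir <- start_dir
  # Jacob's criterion: stop on re-entering the start from an already-seen
  # direction (state repeat); guarantees termination on 1-px-wide arms, where
  # the walk legitimately passes through the start more than once
  seen_at_start <- rep(FALSE, 8L)
  seen_at_start[start_dir] <- TRUE
  repeat {
    path[[length(path) + 1L]] <- cur
    found <- FALSE
    # scan the Moore neighborhood clockwise starting just after the backtrack
    for (k in seq_len(8L)) {
      d <- (dir + k - 1L) %% 8L + 1L
      cand <- cur + .moore[d, ]
      if (m[cand[1], cand[2]]) {
        # new backtrack: the neighbor we examined just before the hit
        prev_d <- (d - 2L) %% 8L + 1L
        prev <- cur + .moore[prev_d, ]
        cur <- cand
        dir <- backtrack_dir(cur, prev)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel inside margin (cannot happen for n > 1 connected)
    if (all(cur == start)) {
      if (seen_at_start[dir]) break
      seen_at_start[dir] <- TRUE
    }
    if (length(path) > 16L * nrow(pts) + 32L) {
      ccrit_abort("boundary tracing failed to terminate; is the blob 8-connected?",
                  "degenerate_geometry")
    }
  }
  out <- do.call(rbind, path)
  out[, 1] <- out[, 1] + r0
  out[, 2] <- out[, 2] + c0
  colnames(out) <- c("row", "col")
  # collapse the duplicate that arises when the walk visits the start twice
  unique_rows_keep_order(out)
}

backtrack_dir <- function(cur, prev) {
  d <- prev - cur
  which(.moore[, 1] == d[1] & .moore[, 2] == d[2])
}

unique_rows_keep_order <- function(m) {
  key <- paste(m[, 1], m[, 2])
  m[!duplicated(key), , drop = FALSE]
}

#' Extract a (row, col) pixel matrix from a blob representation
#' @noRd
blob_pixels <- function(blob) {
  if (is.matrix(blob)) {
    pts <- blob
  } else if (is.data.frame(blob) && "pixels" %in% names(blob)) {
    if (nrow(blob) != 1L) {
      ccrit_abort("supply a single blob (one row of a blob tibble)", "type_error")
    }
    pts <- blob$pixels[[1]]
  } else if (is.list(blob) && !is.null(blob$pixels)) {
    pts <- blob$pixels
  } else {
    ccrit_abort("cannot interpret `blob`; supply pixel coordinates", "type_error")
  }
  storage.mode(pts) <- "integer"
  pts[, 1:2, drop = FALSE]
}
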