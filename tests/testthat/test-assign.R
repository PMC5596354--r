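# Distance profiles, the near/far cutoff, counter-clockwise numbering, and
# full ommatidium assignment.

test_that("distance profiles are sorted Euclidean distances, stable on ties", {
  prof <- distance_profile(c(0, 0), rbind(c(3, 4), c(6, 8)))
  expect_equal(prof$distance, c(5, 10))
  expect_equal(prof$nucleus, c(1L, 2L))

  # anchor at origin, nuclei on the unit circle
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  circ <- cbind(sin(ang), cos(ang))
  expect_equal(distance_profile(c(0, 0), circ)$distance, rep(1, 8))

  withr::with_seed(13, {
    pts <- matrix(stats::runif(40, -50, 50), ncol = 2)
    anchor <- stats::runif(2, -50, 50)
  })
  prof <- distance_profile(anchor, pts)
  oracle <- sort(vapply(seq_len(20), function(i) {
    sqrt(sum((pts[i, ] - anchor)^2))  # per-pair hand computation
  }, numeric(1)))
  expect_equal(prof$distance, oracle)
})

test_that("near cutoff finds the dominant gap", {
  d <- sort(c(1, 1.1, 1, 1.05, 1.1, 1, 1.02, 9.8, 10.1, 10.4))
  expect_equal(near_cutoff(d), 7L)
  expect_equal(near_cutoff(c(1, 50)), 1L)
  expect_equal(near_cutoff(rep(3, 5)), 5L)       # no gap -> min(length, 7)
  expect_equal(near_cutoff(rep(3, 12)), 7L)      # fallback capped at 7
  expect_equal(near_cutoff(c(1:7, 100:104)), 7L) # gap at index 7
})

test_that("counter-clockwise numbering starts at image east", {
  anchor <- c(10, 10)
  # compass E, N, W, S of the anchor -> 1, 2, 3, 4
  cells <- rbind(c(10, 15), c(5, 10), c(10, 5), c(15, 10))
  expect_equal(number_cells_ccw(anchor, cells), 1:4)
  expect_equal(number_cells_ccw(anchor, rbind(c(2, 2))), 1L)
  expect_error(number_cells_ccw(anchor, rbind(c(1, 1), c(1, 1))),
               class = "ccrit_degenerate_geometry")
})

test_that("numbering is rotation-consistent (cyclic shift under common rotation)", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      k <- sample(3:7, 1)
      ang <- sort(stats::runif(k, 0, 2 * pi))
      r <- stats::runif(k, 5, 15)
      cells <- cbind(-r * sin(ang), r * cos(ang))
      n0 <- number_cells_ccw(c(0, 0), cells)
      # brute-force angular sort oracle
      oracle <- order(order(atan2(-cells[, 1], cells[, 2]) %% (2 * pi)))
      expect_equal(n0, oracle)
      theta <- stats::runif(1, 0, 2 * pi)
      rot <- cbind(-(r * sin(ang + theta)), r * cos(ang + theta))
      n1 <- number_cells_ccw(c(0, 0), rot)
      # same cyclic order: successor relations are preserved
      succ0 <- n0[order(n0)]; succ1 <- n1[order(n1)]
      ord0 <- order(n0); ord1 <- order(n1)
      expect_true(any(vapply(seq_len(k), function(s) {
        all(ord1 == c(ord0[-seq_len(s)], ord0[seq_len(s)])) || all(ord1 == ord0)
      }, logical(1))))
    }
  })
})

test_that("two disjoint rings of seven assign cleanly to their own anchors", {
  mk_ring <- function(center, radius = 30) {
    ang <- 2 * pi * (0:6) / 7
    tibble::tibble(
      label = seq_len(7),
      area = 50, convex_area = 50, solidity = 1,
      centroid_row = center[1] - radius * sin(ang),
      centroid_col = center[2] + radius * cos(ang),
      touches_border = FALSE,
      pixels = purrr::map(seq_len(7), ~ matrix(c(1L, 1L), 1))
    )
  }
  n1 <- mk_ring(c(60, 60)); n1$label <- 1:7
  n2 <- mk_ring(c(60, 200)); n2$label <- 8:14
  nuclei <- dplyr::bind_rows(n1, n2)
  anchors <- tibble::tibble(
    label = 1:2, area = 100, convex_area = 100, solidity = 1,
    centroid_row = c(60, 60), centroid_col = c(60, 200),
    touches_border = FALSE,
    pixels = purrr::map(1:2, ~ matrix(c(1L, 1L), 1))
  )
  cm <- assign_ommatidia(anchors, nuclei)
  expect_equal(nrow(cm), 14L)
  expect_equal(length(attr(cm, "unassigned")), 0L)
  expect_equal(sort(unique(cm$ommatidium_label)), c("A", "B"))
  # all of ring 1 under the left anchor (row-major: both rows equal, A = left)
  expect_true(all(cm$ommatidium_label[cm$nucleus_label %in% 1:7] == "A"))
  expect_true(all(cm$ommatidium_label[cm$nucleus_label %in% 8:14] == "B"))
  # consecutive CCW numbers 1..7 in each
  for (lab in c("A", "B")) {
    expect_equal(sort(cm$cell_number[cm$ommatidium_label == lab]), 1:7)
  }
})

test_that("equidistant nuclei tie to the earlier label and distant ones are excluded", {
  blob_row <- function(lab, r, c) {
    tibble::tibble(label = lab, area = 10, convex_area = 10, solidity = 1,
                   centroid_row = r, centroid_col = c, touches_border = FALSE,
                   pixels = list(matrix(c(1L, 1L), 1)))
  }
  anchors <- dplyr::bind_rows(blob_row(1L, 50, 40), blob_row(2L, 50, 160))
  # near sets within ~10 px; one nucleus exactly midway (60 px from each);
  # one nucleus 300+ px from both anchors
  nuclei <- dplyr::bind_rows(
    blob_row(1L, 50, 45), blob_row(2L, 44, 40), blob_row(3L, 56, 40),
    blob_row(4L, 50, 155), blob_row(5L, 44, 160), blob_row(6L, 56, 160),
    blob_row(7L, 50, 100),   # equidistant
    blob_row(8L, 400, 400)   # distant
  )
  withr::with_options(list(ccrit.verbose = FALSE), {
    cm <- assign_ommatidia(anchors, nuclei, gap_factor = 3)
  })
  expect_equal(cm$ommatidium_label[cm$nucleus_label == 7L], "A")
  expect_false(8L %in% cm$nucleus_label)
  expect_equal(attr(cm, "unassigned"), 8L)
  expect_error(assign_ommatidia(anchors[0, ], nuclei), class = "ccrit_assignment_error")
})

test_that("assignment is deterministic and never assigns a nucleus twice", {
  withr::with_seed(55, {
    anchors <- tibble::tibble(
      label = 1:3, area = 10, convex_area = 10, solidity = 1,
      centroid_row = stats::runif(3, 20, 200),
      centroid_col = stats::runif(3, 20, 200),
      touches_border = FALSE,
      pixels = purrr::map(1:3, ~ matrix(c(1L, 1L), 1))
    )
    nuclei <- tibble::tibble(
      label = 1:25, area = 10, convex_area = 10, solidity = 1,
      centroid_row = stats::runif(25, 0, 220),
      centroid_col = stats::runif(25, 0, 220),
      touches_border = FALSE,
      pixels = purrr::map(1:25, ~ matrix(c(1L, 1L), 1))
    )
  })
  withr::with_options(list(ccrit.verbose = FALSE), {
    a <- assign_ommatidia(anchors, nuclei)
    b <- assign_ommatidia(anchors, nuclei)
  })
  expect_identical(a$nucleus_label, b$nucleus_label)
  expect_identical(a$cell_number, b$cell_number)
  expect_equal(anyDuplicated(a$nucleus_label), 0L)
  expect_true(all(table(a$ommatidium_label) <= 7L))
})
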