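# MIP, candidate thresholds, nucleus/background masks, weighted solidity and
# mask refinement.

test_that("MIP is the per-pixel maximum over slices", {
  st0 <- image_stack(lapply(1:3, function(k) matrix(0, 6, 6)), "NUCLEUS")
  expect_equal(max_intensity_projection(st0), matrix(0, 6, 6))

  stk <- image_stack(lapply(1:5, function(k) matrix(k, 4, 4)), "NUCLEUS")
  expect_equal(max_intensity_projection(stk), matrix(5, 4, 4))

  withr::with_seed(21, {
    slices <- lapply(1:4, function(k) matrix(stats::runif(64, 0, 100), 8, 8))
  })
  st <- image_stack(slices, "NUCLEUS")
  mip <- max_intensity_projection(st)
  # brute-force per-pixel loop oracle
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- max(vapply(slices, function(s) s[i, j], numeric(1)))
  }
  expect_equal(mip, oracle)
  # MIP dominates every slice; 1-slice MIP is the slice
  for (s in slices) expect_true(all(mip >= s))
  expect_equal(max_intensity_projection(image_stack(slices[1], "NUCLEUS")),
               slices[[1]])
})

test_that("candidate thresholds are equal-width bin upper edges", {
  img <- matrix(c(0, 100), 1)
  th <- candidate_thresholds(img, 100L)
  expect_equal(th, as.numeric(1:100))
  expect_equal(candidate_thresholds(matrix(c(10, 20), 1), 100L)[50], 15)
  for (seed in 1:10) {
    rng <- sort(withr::with_seed(seed, stats::runif(2, -5, 500)))
    img <- matrix(rng, 1)
    th <- candidate_thresholds(img, 77L)
    expect_true(all(diff(th) > 0))
    expect_equal(th[77], rng[2])
  }
  expect_error(candidate_thresholds(matrix(3, 2, 2)), class = "ccrit_degenerate_range")
})

test_that("nucleus mask thresholds the MIP at the central bin", {
  mip <- matrix(0, 20, 20)
  mip[3:6, 3:6] <- 200
  mip[12:15, 12:15] <- 200
  m <- nucleus_mask(mip, 100L)  # central threshold 100
  expect_type(m, "logical")
  expect_equal(dim(m), dim(mip))
  expect_equal(m, mip == 200)

  ramp <- matrix(seq(0, 100, length.out = 100), 10, 10)
  mr <- nucleus_mask(ramp, 100L)
  expect_equal(mr, ramp > 50)  # strictly above the midpoint
})

test_that("nucleus mask pixel set shrinks as the threshold index increases", {
  withr::with_seed(5, mip <- matrix(stats::runif(400, 0, 255), 20, 20))
  th <- candidate_thresholds(mip, 20L)
  prev <- matrix(TRUE, 20, 20)
  for (t in th) {
    cur <- mip > t
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("weighted solidity matches the direct formula oracle", {
  for (seed in 1:12) {
    m <- random_binary(25, 25, density = 0.3, seed = 600 + seed)
    if (!any(m)) next
    ws <- weighted_solidity(m, 8L)
    b <- label_blobs(m, 8L)
    oracle <- sum(b$area * b$solidity) / sum(b$area)
    expect_equal(ws$weighted_solidity, oracle, tolerance = 1e-9)
    expect_equal(ws$n_blobs, nrow(b))
    # single-blob identity: weighting reduces to that blob's solidity
    if (nrow(b) == 1L) expect_equal(ws$weighted_solidity, b$solidity)
  }
})

test_that("background candidates score below-threshold masks and drop empty ones", {
  mip <- matrix(0, 16, 16)
  mip[4:12, 4:12] <- 100
  mip[1, 1] <- 10  # some intermediate level
  cand <- background_candidates(mip, 10L, 8L)
  # thresholds at or below the global minimum produce empty masks -> excluded
  expect_true(all(cand$threshold > min(mip)))
  # recompute each candidate independently
  for (i in seq_len(nrow(cand))) {
    m <- mip < cand$threshold[i]
    ws <- weighted_solidity(m, 8L)
    expect_equal(cand$weighted_solidity[i], ws$weighted_solidity)
    expect_equal(cand$n_blobs[i], ws$n_blobs)
  }
  expect_error(background_candidates(matrix(1, 4, 4), 10L),
               class = "ccrit_degenerate_range")
})

test_that("background selection is the exhaustive argmin with low-threshold ties", {
  # synthetic MIP: ragged bright nuclei on a dark field
  withr::with_seed(31, {
    mip <- matrix(20 + stats::rnorm(64 * 64, 0, 0.2), 64, 64)
    for (k in 1:5) {
      r <- sample(10:54, 1); c <- sample(10:54, 1)
      for (i in -6:6) for (j in -6:6) {
        if (i^2 + j^2 <= 36 + 6 * sin(3 * atan2(j, i))) {
          mip[r + i, c + j] <- 180
        }
      }
    }
  })
  mip <- round(mip)
  cand <- background_candidates(mip, 100L, 8L)
  sel <- select_background_mask(cand, mip, 8L)
  # brute-force argmin over independently recomputed weighted solidities
  ws_all <- vapply(cand$threshold, function(t) {
    weighted_solidity(mip < t, 8L)$weighted_solidity
  }, numeric(1))
  expect_equal(sel$threshold, cand$threshold[which.min(ws_all)])
  expect_equal(sel$mask, mip < sel$threshold)
  # two-candidate argmin and the single-candidate identity
  two <- tibble::tibble(threshold = c(5, 9), weighted_solidity = c(0.7, 0.4),
                        n_blobs = c(1L, 1L), total_area = c(10, 10))
  expect_equal(select_background_mask(two, mip)$threshold, 9)
  one <- two[1, ]
  expect_equal(select_background_mask(one, mip)$threshold, 5)
})

test_that("refinement removes small blobs, erodes, and fills small holes", {
  cfg <- run_config()
  m <- matrix(FALSE, 100, 100)
  # isolated blob of area ~40 (< 50): a 6x7 rectangle, removed by area filter
  m[3:8, 3:9] <- TRUE
  # large disc of radius 35 with a ~100 px central hole; erosion dilates the
  # hole (radius ~5.5 + 10) but the disc ring survives, then infill closes it
  for (i in 1:100) for (j in 1:100) {
    if ((i - 55)^2 + (j - 55)^2 <= 35^2) m[i, j] <- TRUE
  }
  hole <- which(outer((1:100) - 55, (1:100) - 55, function(a, b) a^2 + b^2) <= 30)
  m[hole] <- FALSE
  out <- refine_background_mask(m, cfg)
  # small blob gone
  expect_false(any(out[1:10, 1:10]))
  # big disc retained (shrunk by erosion) and its hole filled
  expect_true(out[55, 55])
  expect_true(sum(out) > 100)
  # hole interior is inside the eroded disc, hence filled
  expect_true(all(out[cbind(55 + c(-2, 0, 2), 55 + c(0, 2, -2))]))

  # empty in, empty out
  expect_equal(refine_background_mask(matrix(FALSE, 10, 10), cfg),
               matrix(FALSE, 10, 10))
})

test_that("holes larger than the infill limit stay open", {
  cfg <- run_config()
  m <- matrix(TRUE, 120, 120)
  big_hole <- outer((1:120) - 60, (1:120) - 60, function(a, b) a^2 + b^2) <= 625
  m[big_hole] <- FALSE  # ~1963 px > 1500
  out <- refine_background_mask(m, cfg)
  expect_false(out[60, 60])
})
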