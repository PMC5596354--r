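# Noise estimation and subtraction, masking, smoothing, per-cell integration,
# slice summaries, and the end-to-end workflow on small synthetic specimens.

test_that("noise estimation is the masked mean", {
  img <- matrix(5, 6, 6)
  mask <- matrix(TRUE, 6, 6)
  expect_equal(estimate_noise(img, mask), 5)
  img2 <- matrix(0, 4, 4); img2[1, 1] <- 2; img2[2, 2] <- 4
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[2, 2] <- TRUE
  expect_equal(estimate_noise(img2, m2), 3)
  withr::with_seed(2, {
    img3 <- matrix(stats::runif(100, 0, 10), 10, 10)
    m3 <- matrix(stats::runif(100) < 0.4, 10, 10)
  })
  acc <- 0; n <- 0
  for (i in 1:10) for (j in 1:10) if (m3[i, j]) { acc <- acc + img3[i, j]; n <- n + 1 }
  expect_equal(estimate_noise(img3, m3), acc / n)
  expect_error(estimate_noise(img3, matrix(FALSE, 10, 10)), class = "ccrit_empty_mask")
})

test_that("noise subtraction floors at zero, element-wise", {
  expect_equal(subtract_noise(matrix(10, 1, 1), 3), matrix(7, 1, 1))
  expect_equal(subtract_noise(matrix(2, 1, 1), 3), matrix(0, 1, 1))
  withr::with_seed(6, img <- matrix(stats::runif(64, 0, 10), 8, 8))
  out <- subtract_noise(img, 4)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(out[i, j], max(img[i, j] - 4, 0))
  }
})

test_that("cell-mask application zeroes extracellular pixels only", {
  withr::with_seed(10, {
    img <- matrix(stats::runif(64), 8, 8)
    m <- matrix(stats::runif(64) < 0.5, 8, 8)
  })
  expect_equal(apply_cell_mask(img, matrix(TRUE, 8, 8)), img)
  expect_equal(apply_cell_mask(img, matrix(FALSE, 8, 8)), matrix(0, 8, 8))
  out <- apply_cell_mask(img, m)
  expect_equal(out[m], img[m])
  expect_true(all(out[!m] == 0))
  expect_error(apply_cell_mask(img, matrix(TRUE, 4, 4)), class = "ccrit_dimension_error")
})

test_that("smoothing preserves constants and interior impulse mass", {
  expect_equal(smooth_image(matrix(3, 20, 20), 0.8), matrix(3, 20, 20))
  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  sm <- smooth_image(imp, 1.5)
  expect_equal(sum(sm), 100, tolerance = 1e-3)  # < 0.1 % mass change
  expect_identical(smooth_image(imp, 0), imp)   # disabled stage is the identity
})

test_that("per-cell integration sums the nucleus-blob pixel sets", {
  cm <- tibble::tibble(
    ommatidium_label = c("A", "A"), cell_number = 1:2,
    pixels = list(
      cbind(c(2L, 2L, 3L, 3L), c(2L, 3L, 2L, 3L)),
      matrix(integer(0), ncol = 2)
    )
  )
  img <- matrix(2.5, 6, 6)
  out <- integrate_cells(img, cm)
  expect_equal(out$integrated_intensity, c(10, 0))
  withr::with_seed(19, img2 <- matrix(stats::runif(36, 0, 9), 6, 6))
  out2 <- integrate_cells(img2, cm)
  acc <- 0
  for (k in 1:4) acc <- acc + img2[cm$pixels[[1]][k, 1], cm$pixels[[1]][k, 2]]
  expect_equal(out2$integrated_intensity[1], acc)
})

test_that("slice summaries implement the three reporting modes", {
  withr::with_seed(23, {
    cells <- tidyr::expand_grid(ommatidium_label = "A", cell_number = 1:3,
                                slice_index = 1:10)
    cells$integrated_intensity <- stats::runif(nrow(cells), 0, 100)
  })
  s <- summarize_cells(cells, c("ALL", "CENTRAL80", "MAX"),
                       n_slices = 10L, max_slice = 4L)
  for (cn in 1:3) {
    v <- cells$integrated_intensity[cells$cell_number == cn]
    expect_equal(s$mean[s$cell_number == cn & s$mode == "ALL"], mean(v))
    expect_equal(s$sd[s$cell_number == cn & s$mode == "ALL"], sd(v))
    # central 80 % of 10 slices = slices 2..9 (8 slices)
    expect_equal(s$mean[s$cell_number == cn & s$mode == "CENTRAL80"], mean(v[2:9]))
    expect_equal(s$mean[s$cell_number == cn & s$mode == "MAX"], v[4])
    expect_true(is.na(s$sd[s$cell_number == cn & s$mode == "MAX"]))
  }
  # single-slice stack: ALL equals MAX
  one <- cells[cells$slice_index == 1, ]
  s1 <- summarize_cells(one, c("ALL", "MAX"), n_slices = 1L, max_slice = 1L)
  expect_equal(s1$mean[s1$mode == "ALL"], s1$mean[s1$mode == "MAX"])
  expect_warning(summarize_cells(one, "CENTRAL80", n_slices = 1L),
                 class = "ccrit_central80_fallback")
})

test_that("the full workflow is deterministic and linear in the FISH signal", {
  withr::local_options(ccrit.verbose = FALSE)
  sp <- synth_specimen(level = 1, params = small_params(), seed = 5)
  res1 <- run_ccrit(sp$nucleus, sp$fish)
  res2 <- run_ccrit(sp$nucleus, sp$fish)
  # bit-identical CSVs across runs
  dir <- withr::local_tempdir()
  write_cell_table(res1, file.path(dir, "a"))
  write_cell_table(res2, file.path(dir, "b"))
  expect_identical(
    unname(tools::md5sum(file.path(dir, "a_cells.csv"))),
    unname(tools::md5sum(file.path(dir, "b_cells.csv")))
  )
  expect_true(all(res1$cells$integrated_intensity >= 0))

  # doubling every FISH pixel approximately doubles cell intensities:
  # noise is estimated from the same doubled frame, so the processed signal
  # scales exactly; quantisation is the only nonlinearity
  fish2 <- image_stack(lapply(sp$fish$slices, function(s) s * 2), "FISH")
  res_d <- run_ccrit(sp$nucleus, fish2)
  m1 <- specimen_mean(res1)$by_ommatidium
  m2 <- specimen_mean(res_d)$by_ommatidium
  expect_equal(m2 / m1, 2, tolerance = 0.05)
})

test_that("per-cell means increase with the planted spot count", {
  withr::local_options(ccrit.verbose = FALSE)
  means <- vapply(c(0, 0.5, 1), function(lv) {
    sp <- synth_specimen(level = lv, params = small_params(), seed = 31)
    specimen_mean(run_ccrit(sp$nucleus, sp$fish))$by_ommatidium
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a zero-transcript specimen quantifies near zero", {
  withr::local_options(ccrit.verbose = FALSE)
  sp0 <- synth_specimen(level = 0, params = small_params(), seed = 8)
  sp1 <- synth_specimen(level = 1, params = small_params(), seed = 8)
  m0 <- specimen_mean(run_ccrit(sp0$nucleus, sp0$fish))$by_ommatidium
  m1 <- specimen_mean(run_ccrit(sp1$nucleus, sp1$fish))$by_ommatidium
  expect_lt(m0, 0.05 * m1)
})
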