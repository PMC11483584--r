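options(tauscape.quiet = TRUE)

test_that("resampling is the identity at target pitch and preserves constants", {
  v <- volume3d(array(runif(5^3), c(5, 5, 5)), 8.3)
  expect_identical(resample_to_standard(v, 8.3), v)

  cv <- volume3d(array(4.2, c(10, 12, 12)), c(8.3, 6.5, 6.5))
  out <- resample_to_standard(cv, 8.3)
  expect_equal(out$pitch_um, rep(8.3, 3))
  expect_equal(dim(out$data), c(10L, round(12 * 6.5 / 8.3), round(12 * 6.5 / 8.3)))
  expect_true(all(abs(out$data - 4.2) < 1e-12))
})

test_that("resampling a linear ramp matches the analytic ramp at interior voxels", {
  d <- c(6, 6, 40)
  pin <- c(8.3, 8.3, 6.5)
  x_um <- (seq_len(d[3]) - 0.5) * pin[3]
  arr <- array(rep(2 + 0.1 * x_um, each = d[1] * d[2]), d)
  v <- volume3d(arr, pin)
  out <- resample_to_standard(v, 8.3)
  x_out <- (seq_len(dim(out$data)[3]) - 0.5) * 8.3
  interior <- x_out >= x_um[1] & x_out <= x_um[length(x_um)]
  got <- out$data[3, 3, interior]
  expect_equal(got, 2 + 0.1 * x_out[interior], tolerance = 1e-6)
})

test_that("Gaussian-mean difference maps constants to exact zero", {
  v <- volume3d(array(7, c(16, 16, 16)), 8.3)
  dv <- gaussian_mean_difference(v, extraction_params())
  expect_true(all(abs(dv$data) < 1e-12))
})

test_that("filter pipeline matches brute-force convolution on a 21^3 impulse", {
  d <- rep(21L, 3)
  arr <- array(0, d)
  arr[11, 11, 11] <- 1
  v <- volume3d(arr, 8.3)
  p <- extraction_params()
  dv <- gaussian_mean_difference(v, p)

  gk <- tauscape:::gaussian_kernel_1d(p$sigma_small_vox)
  w <- 11L  # round(83 / 8.3) = 10, forced odd
  g3 <- outer(outer(gk, gk), gk)
  m3 <- array(1 / w^3, rep(w, 3))
  expected <- brute_convolve3(arr, g3) - brute_convolve3(arr, m3)
  expect_equal(dv$data, expected, tolerance = 1e-6)
  # impulse center value has the closed form G(0)^3 - 1/w^3
  expect_equal(dv$data[11, 11, 11], gk[(length(gk) + 1) / 2]^3 - 1 / w^3,
               tolerance = 1e-12)
})

test_that("filter pipeline matches brute-force convolution on random volumes", {
  set.seed(11)
  p <- extraction_params(sigma_small_vox = 1.1, mean_extent_um = 5 * 8.3)
  gk <- tauscape:::gaussian_kernel_1d(1.1)
  g3 <- outer(outer(gk, gk), gk)
  m3 <- array(1 / 5^3, rep(5L, 3))
  for (rep_i in 1:2) {
    arr <- array(runif(12^3) * 50, rep(12L, 3))
    dv <- gaussian_mean_difference(volume3d(arr, 8.3), p)
    expected <- brute_convolve3(arr, g3) - brute_convolve3(arr, m3)
    expect_equal(dv$data, expected, tolerance = 1e-6)
  }
})

test_that("small Gaussian FWHM at defaults is approximately 16 um", {
  expect_equal(gaussian_fwhm_um(0.83, 8.3), 2 * sqrt(2 * log(2)) * 0.83 * 8.3)
  expect_lt(abs(gaussian_fwhm_um() - 16), 0.3)
})

test_that("brain mask: threshold keeps the bright block, erosion peels one layer per pass", {
  arr <- array(0, c(50, 50, 50))
  arr[11:40, 11:40, 11:40] <- 10
  v <- volume3d(arr, 8.3)
  m <- compute_brain_mask(v, extraction_params(erosion_iterations = 10))
  expect_equal(m$n_voxels_inside, 10^3)
  expect_true(all(m$mask[21:30, 21:30, 21:30]))

  m0 <- compute_brain_mask(v, extraction_params(erosion_iterations = 0))
  expect_equal(m0$n_voxels_inside, 30^3)
  expect_identical(m0$mask, arr > 1.5 * mean(arr))

  z <- compute_brain_mask(volume3d(array(0, c(8, 8, 8)), 8.3),
                          extraction_params())
  expect_equal(z$n_voxels_inside, 0L)
})

test_that("component labelling agrees with a flood-fill oracle on random grids", {
  set.seed(5)
  for (i in 1:100) {
    fg <- array(runif(8^3) < 0.35, rep(8L, 3))
    for (conn in c(6L, 26L)) {
      expect_true(same_partition(label_components(fg, conn),
                                 flood_fill_label(fg, conn)),
                  info = sprintf("grid %d conn %d", i, conn))
    }
  }
})

test_that("face- vs corner-touching blobs split per connectivity rule", {
  fg <- array(FALSE, c(5, 5, 5))
  fg[2, 2, 2] <- TRUE
  fg[3, 2, 2] <- TRUE  # face neighbour
  expect_equal(max(label_components(fg, 6L)), 1L)
  expect_equal(max(label_components(fg, 26L)), 1L)

  fg2 <- array(FALSE, c(5, 5, 5))
  fg2[2, 2, 2] <- TRUE
  fg2[3, 3, 3] <- TRUE  # corner neighbour
  expect_equal(max(label_components(fg2, 6L)), 2L)
  expect_equal(max(label_components(fg2, 26L)), 1L)
})

test_that("extraction recovers planted blobs with sub-voxel centroid error", {
  scene <- make_test_scene(n_blobs = 20L, seed = 42L)
  p <- extraction_params()
  std <- resample_to_standard(scene$sim$volume, 8.3)
  dv <- gaussian_mean_difference(std, p)
  mask <- compute_brain_mask(std, p)
  spots <- extract_spots(dv, std, mask, p)

  expect_equal(nrow(spots), 20L)
  # conservation: candidate voxels fully partitioned into spots
  expect_equal(sum(spots$volume_vox), attr(spots, "n_candidate_voxels"))
  # each planted center matched by one centroid within 1 voxel (8.3 um)
  cent <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  truth_um <- (scene$centers - 0.5) * 8.3
  for (j in seq_len(nrow(truth_um))) {
    dmin <- min(sqrt(rowSums(sweep(cent, 2, truth_um[j, ])^2)))
    expect_lt(dmin, 8.3)
  }
})

test_that("raising the spot threshold never increases candidate voxels", {
  scene <- make_test_scene(n_blobs = 10L, seed = 9L, shape = c(48, 48, 48))
  std <- resample_to_standard(scene$sim$volume, 8.3)
  prev <- Inf
  for (f in c(1, 2, 4, 8, 16)) {
    p <- extraction_params(spot_threshold_factor = f)
    dv <- gaussian_mean_difference(std, p)
    mask <- compute_brain_mask(std, p)
    spots <- extract_spots(dv, std, mask, p)
    n <- attr(spots, "n_candidate_voxels")
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("end-to-end extraction is deterministic and handles empty volumes", {
  scene <- make_test_scene(n_blobs = 5L, seed = 3L, shape = c(48, 48, 48))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  run_extraction(scene$sim$volume, f1)
  run_extraction(scene$sim$volume, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(read_spot_table(f1)), 5L)

  fz <- withr::local_tempfile(fileext = ".csv")
  zero <- volume3d(array(0, c(16, 16, 16)), 8.3)
  expect_warning(run_extraction(zero, fz), "no tau spots")
  expect_equal(nrow(read_spot_table(fz)), 0L)
})
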