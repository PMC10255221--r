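make_flat_cube <- function(rows, cols, bands, value = 1, mode = "VISNIR",
                           exposure = 50) {
  hypercube(array(value, c(rows, cols, bands)),
            seq(419, 1007, length.out = bands), mode, exposure_ms = exposure)
}

test_that("white/dark calibration satisfies its endpoint identities", {
  raw <- make_flat_cube(8, 6, 5, value = 0.7)
  white <- matrix(0.9, 8, 5)
  dark <- matrix(0.1, 8, 5)

  raw$data[] <- 0.9
  expect_equal(max(abs(calibrate_cube(raw, white, dark)$data - 1)), 0)
  raw$data[] <- 0.1
  expect_equal(max(abs(calibrate_cube(raw, white, dark)$data)), 0)
  raw$data[] <- 0.5 # midpoint of white and dark
  expect_equal(max(abs(calibrate_cube(raw, white, dark)$data - 0.5)), 0)

  bad_white <- white; bad_white[, 3] <- 0.05 # below dark at band 3
  expect_error(calibrate_cube(raw, bad_white, dark), "band\\(s\\) 3")
})

test_that("exposure scaling is linear and invertible", {
  cube <- make_flat_cube(4, 4, 3, value = 2, exposure = 50)
  scaled <- scale_for_exposure(cube, 300)
  expect_equal(scaled$data, cube$data * 6)
  expect_equal(scaled$exposure_ms, 300)

  expect_equal(scale_for_exposure(cube, 50)$data, cube$data)
  round_trip <- scale_for_exposure(scale_for_exposure(cube, 300), 50)
  expect_equal(round_trip$data, cube$data, tolerance = 1e-12)
  cube$exposure_ms <- 50
  expect_error(scale_for_exposure(cube, -1), "positive")
})

test_that("masking recovers the generated fillet footprint", {
  cube <- simulate_hypercube("FL", 3, default_params, seed = 11,
                             rows = 120, cols = 100)
  truth <- attr(cube, "foreground")
  mask <- build_mask(cube, threshold = 0.2)
  tp <- sum(mask & truth)
  expect_gte(tp / sum(mask), 0.99)  # precision
  expect_gte(tp / sum(truth), 0.99) # recall
  expect_lte(sum(mask), prod(dim(mask)))

  flat <- make_flat_cube(10, 10, 4, value = 0.2)
  expect_error(build_mask(flat), "contrast|foreground")
})

test_that("voxelization averages complete tiles and respects the in-mask rule", {
  # full-geometry arithmetic: 500 x 280 at block 10 -> 50 x 28 voxels
  cube <- make_flat_cube(500, 280, 2, value = 3)
  full <- matrix(TRUE, 500, 280)
  tab <- voxelize(cube, full, 10)
  expect_identical(nrow(tab), 1400L)
  expect_true(all(abs(spectra_matrix(tab) - 3) == 0))
  expect_lte(nrow(tab), 50 * 28)

  # block 1 is the identity
  small <- hypercube(array(seq_len(4 * 3 * 2), c(4, 3, 2)),
                     c(500, 600), "FL")
  t1 <- voxelize(small, matrix(TRUE, 4, 3), 1)
  expect_identical(nrow(t1), 12L)
  expect_equal(sort(spectra_matrix(t1)[, 1]), as.numeric(1:12))

  # tiles less than half inside the mask are dropped
  m <- matrix(TRUE, 20, 20)
  m[1:10, 1:10][seq_len(100) %in% sample(100, 60)] <- FALSE # tile 1 < 50%
  cube20 <- make_flat_cube(20, 20, 2)
  expect_identical(nrow(voxelize(cube20, m, 10)), 3L)

  expect_error(voxelize(cube20, m, 25), "larger than the image")
})

test_that("the >10%/2-SD rule excludes exactly the planted saturated voxels and is idempotent", {
  cube <- simulate_hypercube("VISNIR", 3, default_params, seed = 5,
                             saturation_fraction = 0.03,
                             rows = 120, cols = 100)
  cal <- calibrate_cube(cube)
  mask <- build_mask(cal, threshold = 0.2)
  tab <- voxelize(cal, mask, 10, day = 3)
  flagged <- flag_outlier_voxels(cal, tab, mask)

  planted <- attr(cube, "saturated_tiles")
  excluded <- flagged[!flagged$kept, c("block_row", "block_col")]
  expect_gt(nrow(planted), 0)
  expect_setequal(paste(excluded$block_row, excluded$block_col),
                  paste(planted$block_row, planted$block_col))

  again <- flag_outlier_voxels(cal, flagged, mask)
  expect_identical(again$kept, flagged$kept)

  # homogeneous cube: no exclusions
  flat <- make_flat_cube(30, 30, 3, value = 0.5, mode = "FL")
  flat$data <- flat$data + array(rnorm(prod(dim(flat$data)), 0, 1e-3),
                                 dim(flat$data))
  fm <- matrix(TRUE, 30, 30)
  ft <- flag_outlier_voxels(flat, voxelize(flat, fm, 10), fm)
  expect_true(all(ft$kept))
})

test_that("the exclusion boundary is strictly greater-than", {
  # one 10x10 voxel; plant exactly 10 far outliers (10%) then 11 (11%)
  base <- matrix(rnorm(400, 10, 1), 20, 20)
  for (n_out in c(10, 11)) {
    img <- base
    img[1:10, 1:10][seq_len(n_out)] <- 60 # gross outliers at band 1
    cube <- hypercube(array(img, c(20, 20, 1)), 500, "FL")
    mask <- matrix(TRUE, 20, 20)
    tab <- flag_outlier_voxels(cube, voxelize(cube, mask, 10), mask)
    target <- tab$kept[tab$block_row == 1 & tab$block_col == 1]
    if (n_out == 10) expect_true(target) else expect_false(target)
  }
})

test_that("SNV and Savitzky-Golay behave as defined", {
  expect_equal(pretreat_spectrum(c(1, 2, 3), "SNV"), c(-1, 0, 1))

  set.seed(1)
  for (i in 1:20) {
    s <- rnorm(60, 10, 3)
    out <- pretreat_spectrum(s, "SNV")
    expect_equal(mean(out), 0, tolerance = 1e-12)
    expect_equal(sd(out), 1, tolerance = 1e-12)
  }
  expect_error(pretreat_spectrum(rep(1, 10), "SNV"), "constant")

  # exact reproduction of a cubic under a cubic-order filter
  x <- seq(-1, 1, length.out = 61)
  cubic <- 2 + x - 0.5 * x^2 + 3 * x^3
  sm <- pretreat_spectrum(cubic, "SavitzkyGolay", window = 11, poly_order = 3)
  expect_equal(sm, cubic, tolerance = 1e-9)
  expect_length(sm, length(cubic))
  expect_error(pretreat_spectrum(cubic, "SavitzkyGolay", window = 10), "odd")
})

test_that("the preprocessing chain runs in its fixed order and logs provenance", {
  cube <- simulate_hypercube("VISNIR", 5, default_params, seed = 9,
                             saturation_fraction = 0.02,
                             rows = 120, cols = 100)
  tab <- preprocess_cube(cube, day = 5)
  expect_s3_class(tab, "voxel_table")
  expect_true(all(tab$kept))
  prov <- attr(tab, "provenance")
  expect_identical(prov$block, 10L)
  expect_identical(prov$outlier_frac, 0.1)
  expect_identical(prov$sd_mult, 2)
  # calibrated reflectance scale
  expect_lt(max(spectra_matrix(tab)), 1.1)
})
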