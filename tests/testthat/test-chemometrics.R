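test_that("PCA eigenvalue fractions normalize and match a direct eigensolver", {
  set.seed(3)
  X <- matrix(rnorm(20), 5, 4)
  res <- pca_fit(X, pretreat = FALSE)
  expect_equal(sum(res$pct_variation), 1)
  # independent oracle: eigendecomposition of the covariance matrix
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(res$eigenvalues, ev[ev > 1e-12], tolerance = 1e-8)

  # loadings orthonormal
  G <- t(res$loadings) %*% res$loadings
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)

  # points on a line: PC1 takes essentially all variation
  t <- rnorm(50)
  line <- cbind(2 * t, -t) + matrix(rnorm(100, 0, 1e-4), 50, 2)
  expect_gte(pca_fit(line, pretreat = FALSE)$pct_variation[1], 0.99)

  expect_error(pca_fit(X[1, , drop = FALSE]), "at least 2")
  expect_error(pca_fit(matrix(1, 4, 3), pretreat = TRUE), "constant")
})

test_that("PC retention rules follow their definitions", {
  expect_identical(select_pc_count(c(3.2, 1.4, 1.1, 0.6, 0.2),
                                   "eigenvalue_gt1"), 3L)
  expect_warning(n0 <- select_pc_count(c(0.9, 0.5), "eigenvalue_gt1"),
                 "no eigenvalue")
  expect_identical(n0, 0L)

  lam <- c(10, 5, 1, 0.9, 0.8)
  elbow <- select_pc_count(lam, "scree")
  # brute-force elbow oracle: maximize the second difference
  d2 <- vapply(2:(length(lam) - 1),
               function(i) lam[i - 1] - 2 * lam[i] + lam[i + 1], numeric(1))
  expect_identical(elbow, as.integer(which.max(d2) + 1L))
  expect_lte(elbow, 3L)
  expect_error(select_pc_count(numeric(0)), "empty")
})

test_that("SOM distances are Euclidean and clusters land on disjoint node sets", {
  expect_identical(spectral_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(spectral_distance(c(0, 0), c(3, 4)), 5)
  expect_error(spectral_distance(1:3, 1:4), "length")

  set.seed(5)
  a <- matrix(rnorm(300, 0, 0.3), 30, 10)
  b <- matrix(rnorm(300, 8, 0.3), 30, 10)
  som <- som_fit(rbind(a, b), 4, 4, epochs = 20, seed = 2)
  # assignments are nearest-codebook
  d2 <- as.matrix(dist(rbind(rbind(a, b), som$codebook)))
  d2 <- d2[1:60, 61:76]
  expect_identical(som$assignments, unname(apply(d2, 1, which.min)))
  # the two clusters occupy disjoint node sets
  expect_length(intersect(unique(som$assignments[1:30]),
                          unique(som$assignments[31:60])), 0L)
  # reproducibility
  som2 <- som_fit(rbind(a, b), 4, 4, epochs = 20, seed = 2)
  expect_identical(som$codebook, som2$codebook)
})

test_that("HCA on SOM codebooks recovers planted spectral archetypes", {
  wl <- mode_wavelengths("FL")
  archetypes <- list(
    two_peak = two_peak_spectrum(wl, dl = 80, ratio = 0.9),
    major_shoulder = two_peak_spectrum(wl, dl = 55, ratio = 1.6),
    minor_shoulder = two_peak_spectrum(wl, dl = 55, ratio = 3.5),
    single_peak = two_peak_spectrum(wl, dl = 55, ratio = 1e6))
  set.seed(8)
  X <- do.call(rbind, lapply(archetypes, function(a)
    t(replicate(15, a + rnorm(60, 0, 0.01)))))
  labels <- rep(names(archetypes), each = 15)

  som <- som_fit(X, 4, 4, epochs = 30, seed = 3)
  # cluster the occupied nodes (empty interpolating nodes carry no spectra)
  occupied <- sort(unique(som$assignments))
  classes <- hca_classes(som$codebook[occupied, ], k = 4)
  spectrum_class <- classes[match(som$assignments, occupied)]
  # each archetype maps to a single class, and the classes are distinct
  per_arch <- vapply(unique(labels), function(l)
    length(unique(spectrum_class[labels == l])), integer(1))
  expect_true(all(per_arch == 1L))
  expect_length(unique(tapply(spectrum_class, labels, unique)), 4L)

  # degenerate k choices
  cb <- som$codebook
  expect_length(unique(hca_classes(cb, k = nrow(cb))), nrow(cb))
  expect_length(unique(hca_classes(cb, k = 1)), 1L)
  expect_error(hca_classes(cb, k = 0), ">= 1")
})

test_that("two-peak deconvolution recovers generator parameters", {
  wl <- mode_wavelengths("FL")
  s <- two_peak_spectrum(wl, dl = 60, ratio = 1 / 0.6, p2_fwhm = 59)
  fit <- fit_two_peak_model(s, wl)
  expect_true(fit$p2_resolved)
  expect_lt(abs(fit$p1_center - 452.6), 0.5)
  expect_lt(abs(fit$p2_center - 512.6), 0.5)
  expect_lt(abs(fit$delta_lambda - 60), 1)

  # single-Gaussian input engages the inflexion fallback
  g <- exp(-0.5 * ((wl - 500) / 20)^2)
  fg <- fit_two_peak_model(g, wl)
  expect_false(fg$p2_resolved)
  expect_gt(fg$delta_lambda_error, 0)

  # P1 position on default synthetic data stays in the stated envelope
  for (d in c(1, 5, 9)) {
    sp <- simulate_spectrum("FL", d, "tail_bottom", default_params,
                            noise_sd = 0)
    expect_lt(abs(fit_two_peak_model(sp, wl)$p1_center - 452.6), 3)
  }
})

test_that("peak-separation recovery holds at realistic noise over many random spectra", {
  wl <- mode_wavelengths("FL")
  set.seed(42)
  err <- replicate(100, {
    dl <- runif(1, 55, 95)
    ratio <- runif(1, 0.8, 1.5)
    fwhm <- runif(1, 103.9, 115.9)
    s <- two_peak_spectrum(wl, dl, ratio, p2_fwhm = fwhm, noise = 1 / 50)
    abs(fit_two_peak_model(s, wl)$delta_lambda - dl)
  })
  expect_lte(median(err), 1)
})

test_that("K and H freshness indices satisfy endpoints, arithmetic and monotonicity", {
  expect_equal(catabolite_indices(list(imp = 1, inosine = 0, hx = 0)),
               c(K = 0, H = 0))
  expect_equal(catabolite_indices(list(imp = 0, inosine = 0, hx = 1)),
               c(K = 1, H = 1))
  expect_equal(catabolite_indices(list(imp = 20, inosine = 60, hx = 20)),
               c(K = 0.8, H = 0.2))
  expect_error(catabolite_indices(list(imp = 0, inosine = 0, hx = 0)),
               "all-zero")

  traj <- t(vapply(seq(0, 14, by = 0.25), function(d)
    catabolite_indices(simulate_catabolites(d, 0.5, 0.3)), numeric(2)))
  expect_true(all(diff(traj[, "K"]) >= -1e-12))
  expect_true(all(diff(traj[, "H"]) >= -1e-12))
})

test_that("the hit quality index is a sum of absolute differences with metric-like behavior", {
  expect_identical(hqi(c(1, 2), c(1, 2)), 0)
  expect_identical(hqi(c(0, 0), c(1, -1)), 2)
  expect_error(hqi(1:3, 1:4), "length")

  set.seed(9)
  x <- rnorm(60); y <- rnorm(60)
  loop <- 0
  for (i in seq_along(x)) loop <- loop + abs(x[i] - y[i])
  expect_equal(hqi(x, y), loop)
  expect_equal(hqi(x, y), hqi(y, x))
  expect_gte(hqi(x, y), 0)
})

test_that("nearest-feature day prediction clamps, tie-breaks early, and is accurate to a day", {
  curve <- calibration_curve(c(1, 3, 5), c(85, 81, 77), "delta_lambda")
  expect_identical(predict_day_from_feature(81, curve), 3)
  expect_identical(predict_day_from_feature(200, curve), 1)  # clamp high
  expect_identical(predict_day_from_feature(0, curve), 5)    # clamp low
  # exact midpoint ties go to the earlier day
  expect_identical(predict_day_from_feature(83, curve), 1)
  expect_error(predict_day_from_feature(1, list()), "calibration_curve")
  expect_error(calibration_curve(numeric(0), numeric(0)), "empty")

  # calibration fillet -> validation fillet recovery within one day
  wl <- mode_wavelengths("FL")
  p <- default_params
  days <- 1:9
  cal_dl <- vapply(days, function(d)
    fit_two_peak_model(simulate_spectrum("FL", d, "tail_bottom", p,
                                         noise_sd = 0), wl)$delta_lambda,
    numeric(1))
  curve <- calibration_curve(days, cal_dl, "delta_lambda")
  set.seed(13)
  for (d in days) {
    val <- simulate_spectrum("FL", d, "tail_bottom", p, noise_sd = 0.005)
    est <- fit_two_peak_model(val, wl)$delta_lambda
    expect_lte(abs(predict_day_from_feature(est, curve) - d), 1)
  }
})
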