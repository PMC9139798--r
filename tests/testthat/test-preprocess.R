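test_that("Savitzky-Golay detrending removes what a cubic filter must", {
  tr <- 0.5
  # constant series is its own trend
  const <- matrix(3, 2, 100)
  out <- savgol_detrend(const, order = 3, frame_length_s = 10.5, tr_s = tr)
  expect_lt(max(abs(out)), 1e-10)
  # an order-3 filter reproduces cubics exactly, edges included here
  # because the asymmetric edge fits are themselves cubic regressions
  t <- seq_len(81)
  cubic <- matrix(0.3 * t^3 - 2 * t^2 + 5 * t - 7, 1)
  out <- savgol_detrend(cubic, order = 3, frame_length_s = 40 * tr, tr_s = tr)
  expect_lt(max(abs(out)) / max(abs(cubic)), 1e-6)
})

test_that("detrending removes slow drift but keeps fast oscillations", {
  tr <- 0.1
  t <- seq(0, 300, by = tr)
  sine <- sin(2 * pi * 0.5 * t)
  drift <- 0.05 * t
  out <- savgol_detrend(matrix(sine + drift, 1), order = 3,
                        frame_length_s = 240, tr_s = tr)
  mid <- seq(500, length(t) - 500)
  amp_ratio <- max(abs(out[1, mid])) / max(abs(sine[mid]))
  expect_gt(amp_ratio, 0.95)
  expect_lt(amp_ratio, 1.05)
  resid_drift <- savgol_detrend(matrix(drift, 1), order = 3,
                                frame_length_s = 240, tr_s = tr)
  expect_lt(max(abs(resid_drift)) / max(abs(drift)), 1e-8)
})

test_that("the matrix smoother agrees with signal::sgolayfilt", {
  set.seed(10)
  x <- cumsum(rnorm(120))
  ours <- x - savgol_detrend(matrix(x, 1), order = 3, frame_length_s = 21,
                             tr_s = 1)[1, ]
  ref <- signal::sgolayfilt(x, p = 3, n = 21)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("detrending errors name the required minimum length", {
  expect_error(savgol_detrend(matrix(0, 1, 50), order = 3,
                              frame_length_s = 24, tr_s = 0.1),
               "need at least 241")
  expect_error(savgol_detrend(matrix(0, 1, 50), order = 3,
                              frame_length_s = 0.2, tr_s = 0.1),
               "exceed the polynomial order")
})

test_that("DVARS matches its definition", {
  # constant series
  expect_equal(compute_dvars(matrix(2, 5, 10))$dvars, rep(0, 9))
  # hand computation: volumes [0,0] then [2,4] -> sd of [2,4] = sqrt(2)
  m <- cbind(c(0, 0), c(2, 4))
  expect_equal(compute_dvars(m)$dvars, sqrt(2), tolerance = 1e-12)
  expect_equal(compute_dvars(m)$mean_dvars, sqrt(2), tolerance = 1e-12)
  # homogeneity of degree one
  set.seed(11)
  x <- matrix(rnorm(20 * 30), 20, 30)
  expect_equal(compute_dvars(3.7 * x)$dvars, 3.7 * compute_dvars(x)$dvars,
               tolerance = 1e-12)
  expect_error(compute_dvars(matrix(1, 4, 1)), "at least 2")
})

test_that("band-pass keeps the passband, kills the stopband, shifts nothing", {
  tr <- 0.1
  t <- seq(0, 60, by = tr)
  passband <- sin(2 * pi * 1 * t)
  out <- bandpass_filter(matrix(passband, 1), 0.08, 4, tr_s = tr)[1, ]
  mid <- seq(100, length(t) - 100)
  expect_gt(max(abs(out[mid])) / max(abs(passband[mid])), 0.9)
  cc <- ccf(out[mid], passband[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  drift <- sin(2 * pi * 0.01 * t)
  out <- bandpass_filter(matrix(drift, 1), 0.08, 4, tr_s = tr)[1, ]
  expect_lt(max(abs(out[mid])) / max(abs(drift[mid])), 0.1)

  expect_equal(bandpass_filter(matrix(0, 3, 200), tr_s = tr),
               matrix(0, 3, 200))
  expect_error(bandpass_filter(matrix(0, 1, 100), 0.08, 5, tr_s = tr),
               "Nyquist")
})

test_that("Gaussian smoothing: identity, mass conservation, kernel oracle", {
  set.seed(12)
  a <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  expect_identical(gaussian_smooth(a, fwhm_mm = 0), a)
  const <- array(1.5, c(12, 12, 12))
  sm <- gaussian_smooth(const, fwhm_mm = 6, voxel_size_mm = 3)
  # voxels with full kernel support see a unit-mass kernel
  expect_lt(max(abs(sm[5:8, 5:8, 5:8] - 1.5)), 1e-10)

  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  sm <- gaussian_smooth(imp, fwhm_mm = 6, voxel_size_mm = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-12)   # mass conserved off-boundary
  oracle <- naive_gaussian_smooth3(imp, 6, 3)
  expect_equal(sm, oracle, tolerance = 1e-10)
  sigma <- (6 / 3) / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 0.8493, tolerance = 1e-4)
  expect_error(gaussian_smooth(a, fwhm_mm = -1), "non-negative")
})

test_that("nuisance regression removes a subject-specific artifact", {
  gd <- tiny_bold(n_per_group = 3, T = 200, seed = 13,
                  artifact_amplitude = 1.5, artifact_gray_bleed = 0.4)
  art <- gd$ground_truth$artifact[[1]][["A1"]]
  gray <- analysis_voxels(gd)
  before <- max(abs(cor(t(gd$data[["A1"]][[1]][gray[1:30], ]), art)))
  expect_gt(before, 0.3)     # the bleed is visible pre-cleanup
  cleaned <- maxcorr_denoise(gd, k = 4)
  after <- max(abs(cor(t(cleaned$data[["A1"]][[1]][gray[1:30], ]), art)))
  expect_lt(after, 0.1)
})

test_that("nuisance regression protects signal shared by all subjects", {
  gd <- tiny_bold(n_per_group = 3, T = 200, seed = 14, shared = 0.5)
  shared_sig <- gd$ground_truth$shared[[1]]
  gray <- analysis_voxels(gd)
  cleaned <- maxcorr_denoise(gd, k = 4)
  vsel <- gray[1:30]
  r_before <- sapply(seq_along(vsel), function(i)
    cor(gd$data[["A1"]][[1]][vsel[i], ], shared_sig[vsel[i], ]))
  r_after <- sapply(seq_along(vsel), function(i)
    cor(cleaned$data[["A1"]][[1]][vsel[i], ], shared_sig[vsel[i], ]))
  expect_gt(mean(r_after) / mean(r_before), 0.9)
})

test_that("cleanup barely moves ISC when there is nothing to remove", {
  gd <- tiny_bold(n_per_group = 3, T = 200, seed = 17, shared = 0.3)
  before <- compute_isc(gd, "A")$aggregated_r
  after <- compute_isc(maxcorr_denoise(gd, k = 4), "A")$aggregated_r
  expect_lt(mean(abs(after - before)), 0.02)
})

test_that("k = 0 is a no-op and impossible k errors", {
  gd <- tiny_bold(seed = 15)
  expect_identical(maxcorr_denoise(gd, k = 0), gd)
  expect_error(maxcorr_denoise(gd, k = 10000), "rank")
})

test_that("the full chain runs in order and reports DVARS per run", {
  gd <- tiny_bold(n_per_group = 2, T = 120, seed = 16)
  out <- preprocess_dataset(gd, sg_frame_s = 8, maxcorr_k = 2,
                            band = c(0.08, 4), fwhm_mm = 6)
  expect_s3_class(out$dataset, "group_dataset")
  expect_equal(nrow(out$dvars), 4 * 2)
  expect_true(all(out$dvars$mean_dvars > 0))
  expect_equal(dim(out$dataset$data[["A1"]][[1]]),
               dim(gd$data[["A1"]][[1]]))
})
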