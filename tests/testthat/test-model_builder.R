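ref_alpha <- shape_params(latency = 0.1, dip = 0.05, rise = 0.1,
                          plateau = 0.2, decay = 0.1, undershoot = 0.05,
                          dip_depth = 0.3, undershoot_depth = 0.2)

test_that("the response shape takes its defining values on every branch", {
  # pre-latency and plateau branches
  expect_equal(response_shape(0.05, ref_alpha), 0)
  expect_equal(response_shape(0.3, ref_alpha), 1)
  # branch endpoints: dip bottom -dip_depth, undershoot bottom
  # -undershoot_depth (closed-form endpoint evaluation)
  expect_equal(response_shape(0.15, ref_alpha), -0.3, tolerance = 1e-12)
  expect_equal(response_shape(0.55, ref_alpha), -0.2, tolerance = 1e-12)
  # past the support
  expect_equal(response_shape(0.61, ref_alpha), 0)

  # zero depths and zero dip/undershoot durations: raised-cosine trapezoid
  trap <- shape_params(latency = 0.1, dip = 0, rise = 0.2, plateau = 0.3,
                       decay = 0.2, undershoot = 0)
  t <- seq(0, 1, by = 1e-3)
  r <- response_shape(t, trap)
  expect_equal(max(r), 1)
  expect_equal(min(r), 0)
  expect_equal(r[t > 0.32 & t <= 0.6], rep(1, sum(t > 0.32 & t <= 0.6)))
})

test_that("the shape is continuous and confined to its stated range/support", {
  withr::local_seed(42)
  t <- seq(0, 3, by = 5e-4)
  for (i in 1:50) {
    p <- random_shape_params()
    r <- response_shape(t, p)
    # no jumps: increments bounded by max slope pi/(2 * shortest segment)
    # times the grid step, with headroom
    expect_lt(max(abs(diff(r))), 2 * pi * 5e-4 / min(as.numeric(p)[2:6]))
    expect_lte(max(r), 1)
    expect_gte(min(r), -max(p[["dip_depth"]], p[["undershoot_depth"]]) - 1e-12)
    support_end <- p[["latency"]] + sum(p[2:6])
    expect_true(all(r[t <= p[["latency"]] | t > support_end + 5e-4] == 0))
  }
})

test_that("the shape library enumerates the parameter grid deterministically", {
  t <- (0:49) / 110

  # all n_steps = 1: a single midpoint shape
  iv1 <- shape_intervals()
  lib1 <- generate_shape_library(iv1, t)
  expect_equal(nrow(lib1), 1)
  expect_equal(as.vector(lib1[1, ]), response_shape(t, shape_params()))

  # sweeping one parameter only: rows differ only in plateau length
  iv2 <- shape_intervals(plateau = c(0.1, 0.3, 2))
  lib2 <- generate_shape_library(iv2, t)
  expect_equal(nrow(lib2), 2)
  p <- attr(lib2, "params")
  expect_equal(sort(p$plateau), c(0.1, 0.3))
  expect_equal(length(unique(p$rise)), 1)

  # combinatorial count: 3 steps on three parameters -> 27 rows
  iv3 <- shape_intervals(rise = c(0.1, 0.3, 3), plateau = c(0.1, 0.5, 3),
                         decay = c(0.1, 0.3, 3))
  expect_equal(nrow(generate_shape_library(iv3, t)), 27)

  # repeated generation is identical (deterministic ordering)
  expect_identical(generate_shape_library(iv3, t),
                   generate_shape_library(iv3, t))

  # cap guard
  expect_error(shape_intervals(rise = c(0.1, 0.3, 100),
                               plateau = c(0.1, 0.5, 100),
                               decay = c(0.1, 0.3, 100), cap = 1e4),
               "cap")
})

test_that("the PCA basis is orthonormal and optimal in the SVD sense", {
  t <- (0:39) / 110
  iv <- shape_intervals(latency = c(0, 0.1, 3), rise = c(0.05, 0.2, 3),
                        plateau = c(0, 0.2, 3), decay = c(0.05, 0.2, 3))
  lib <- generate_shape_library(iv, t)

  # single shape: the normalized shape itself
  one <- lib[1, , drop = FALSE]
  b1 <- shape_basis(one, L = 1)
  expect_equal(as.vector(b1), as.vector(one / sqrt(sum(one^2))),
               tolerance = 1e-12)

  # orthonormality and sign convention
  B <- shape_basis(lib, L = 6)
  expect_equal(crossprod(B), diag(6), tolerance = 1e-10)
  for (j in 1:6) expect_gt(B[which.max(abs(B[, j])), j], 0)

  # SVD optimality oracle: total reconstruction error at L equals the tail
  # singular-value energy, and is non-increasing in L
  sv <- svd(lib)
  errs <- vapply(1:8, function(L) {
    BL <- shape_basis(lib, L = L)
    sum((lib - lib %*% BL %*% t(BL))^2)
  }, numeric(1))
  tails <- vapply(1:8, function(L) sum(sv$d[-(1:L)]^2), numeric(1))
  expect_equal(errs, tails, tolerance = 1e-8)
  expect_true(all(diff(errs) <= 1e-10))

  # orthogonal rows span: projection residual 0 at L = n_rows
  orth <- diag(1, 4, 40)
  Bo <- shape_basis(orth, L = 4)
  expect_lt(max(abs(orth - orth %*% Bo %*% t(Bo))), 1e-10)

  expect_error(shape_basis(lib, L = 0), "L must")
  expect_error(shape_basis(lib, L = 1000), "L must")
})

test_that("tau and heartbeat frequency are estimated from blank timecourses", {
  fs <- 110
  t <- (0:219) / fs

  # noiseless constant + exponential with tau on the grid: exact recovery
  y <- 5 + 0.3 * exp(-t / 2)
  est <- estimate_tau_and_heartbeat(y + 0.001 * sin(2 * pi * 3 * t), fs,
                                    tau_grid = c(0.5, 1, 2, 4, 8))
  expect_equal(est$tau, 2)

  # periodogram oracle: a pure 2.5 Hz sinusoid at 110 Hz over 2 s falls in
  # the 2.5 Hz bin exactly (resolution fs/T = 0.5 Hz)
  y2 <- sin(2 * pi * 2.5 * t)
  est2 <- estimate_tau_and_heartbeat(y2, fs)
  a <- Mod(fft(est2$residual))[2:110]
  f_oracle <- (which.max(a)) * fs / 220
  expect_equal(est2$f_heart, f_oracle)
  expect_equal(est2$f_heart, 2.5, tolerance = 0.5)

  # constant timecourse: flagged, not silent
  expect_warning(est3 <- estimate_tau_and_heartbeat(rep(3, 64), fs),
                 "no oscillation")
  expect_true(is.na(est3$f_heart))

  expect_error(estimate_tau_and_heartbeat(y, fs, heart_band = c(60, 80)),
               "empty")
  expect_error(estimate_tau_and_heartbeat(y[1:8], fs), "too short")
})

test_that("spectral peaks find strong oscillations and ignore white noise", {
  fs <- 110
  t <- (0:511) / fs

  # two sinusoids far above the noise floor: both recovered within one bin
  y <- 3 * sin(2 * pi * 2.5 * t) + 2 * sin(2 * pi * 7.3 * t + 1) +
    0.01 * rnorm(512)
  pk <- spectral_peaks(y, fs)
  expect_gte(length(pk), 2)
  expect_lt(min(abs(pk - 2.5)), fs / 512)
  expect_lt(min(abs(pk - 7.3)), fs / 512)
  # sorted by descending amplitude: the 2.5 Hz peak is stronger
  expect_lt(abs(pk[1] - 2.5), fs / 512)

  # excluded band covering the whole spectrum: nothing returned
  expect_length(spectral_peaks(y, fs, exclude_bands = list(c(0, 55))), 0)

  # Monte-Carlo calibration: white noise yields (almost) no false peaks
  withr::local_seed(9)
  n_empty <- sum(vapply(1:100, function(i) {
    length(spectral_peaks(rnorm(256), fs, z_threshold = 8)) == 0
  }, logical(1)))
  expect_gte(n_empty, 95)
})

test_that("the design matrix has the declared layout and refuses degeneracy", {
  # no noise, no shapes: single constant column
  d0 <- build_design_matrix(50, 110, 10, noise_spec())
  expect_equal(ncol(d0$X), 1)
  expect_equal(d0$partition$constant, 1L)
  expect_length(d0$partition$noise, 0)

  # column count: constant + exp + sin/cos + 3 shapes = 7
  sb <- make_signal_block(shape_intervals(), 50, 110, 10, L = 1)
  sb <- cbind(sb, 0, 0)  # pad to 3 columns for the count check
  sb[11:50, 2] <- sin((1:40) / 7); sb[11:50, 3] <- cos((1:40) / 9)
  d1 <- build_design_matrix(50, 110, 10,
                            noise_spec(tau = 5, oscillation_freqs = 3,
                                       n_harmonics = 1), sb)
  expect_equal(ncol(d1$X), 7)
  expect_equal(d1$labels[1], "constant")
  expect_equal(d1$partition$noise, 2:4)
  expect_equal(d1$partition$signal, 5:7)
  expect_true(all(d1$X[1:10, d1$partition$signal[1]] == 0))

  # duplicate frequency: rank-deficiency error naming columns
  expect_error(build_design_matrix(50, 110, 10,
                                   noise_spec(oscillation_freqs = c(3, 3),
                                              n_harmonics = 1)),
               "rank deficient")
  # harmonic at/above Nyquist
  expect_error(build_design_matrix(50, 110, 10,
                                   noise_spec(oscillation_freqs = 30,
                                              n_harmonics = 2)),
               "Nyquist")
})

test_that("design matrices serialize and read back losslessly", {
  dir <- withr::local_tempdir()
  sb <- make_signal_block(study_intervals(), 60, 110, 10, L = 3)
  des <- build_design_matrix(60, 110, 10,
                             noise_spec(tau = 2, oscillation_freqs = 2.5,
                                        n_harmonics = 2), sb)
  p <- file.path(dir, "design.tsv")
  write_design_matrix(des, p)
  des2 <- read_design_matrix(p)
  expect_equal(unname(des2$X), unname(des$X), tolerance = 1e-12)
  expect_equal(des2$labels, des$labels)
  expect_equal(des2$partition, lapply(des$partition, as.integer))
  expect_equal(des2$info$frequencies, des$info$frequencies)
})
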