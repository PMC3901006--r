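test_that("ROI timecourses are unweighted means over the mask", {
  arr <- array(rnorm(4 * 4 * 6), c(4, 4, 6))

  # single-pixel mask: that pixel's series
  m1 <- matrix(FALSE, 4, 4); m1[2, 3] <- TRUE
  expect_equal(roi_timecourse(arr, roi(m1)), arr[2, 3, ])

  # uniform stack: constant
  u <- array(0.7, c(4, 4, 6))
  expect_equal(roi_timecourse(u, roi_disk(4, 4, c(2, 2), 2)), rep(0.7, 6))

  # two-pixel mask: brute-force mean oracle
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[4, 2] <- TRUE
  expect_equal(roi_timecourse(arr, roi(m2)),
               (arr[1, 1, ] + arr[4, 2, ]) / 2, tolerance = 1e-12)

  expect_error(roi(matrix(FALSE, 2, 2)), "no pixels")
  expect_error(roi_timecourse(arr, roi_disk(8, 8, c(4, 4), 2)),
               "do not match")

  # NaN pixels are excluded with a message
  arr[1, 1, ] <- NaN
  expect_message(tc <- roi_timecourse(arr, roi(m2)), "excluded")
  expect_equal(tc, arr[4, 2, ])
})

test_that("ROI label images round-trip through NIfTI", {
  r <- roi_disk(6, 9, c(3, 4), 2.5, label = "v1")
  p <- file.path(withr::local_tempdir(), "v1.nii.gz")
  write_roi(r, p)
  r2 <- read_roi(p)
  expect_equal(r2$mask, r$mask)
})

test_that("condition averages reduce trials with flagged degenerate sd", {
  arr <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  r <- roi_disk(4, 4, c(2.5, 2.5), 2)

  one <- condition_average(list(arr), codes = 3, condition = 3, r)
  expect_equal(one$mean, roi_timecourse(arr, r))
  expect_equal(one$sd, rep(0, 5))
  expect_true(one$single_trial)

  two <- condition_average(list(arr, arr), codes = c(1, 1), 1, r)
  expect_equal(two$sd, rep(0, 5))
  expect_false(two$single_trial)
  expect_equal(two$n, 2)

  expect_error(condition_average(list(arr), codes = 1, condition = 9, r),
               "no trials")
})

test_that("condition-mean peaks are ordered by configured amplitude", {
  ses <- tiny_session()
  des <- study_design(ses, L = 4)
  cf <- ses$truth$config
  sched <- ses$truth$schedule
  stim <- stim_index(ses)
  dffs <- lapply(stim, function(k) fit_glm(ses$trials[[k]], des)$dff)
  r <- roi_disk(cf$H, cf$W, cf$roi_center, 3)
  peaks <- vapply(1:2, function(cc) {
    max(condition_average(dffs, sched$condition[stim], cc, r)$mean)
  }, numeric(1))
  expect_true(peaks[2] > peaks[1])
})

test_that("trial variability reports dispersion and honors amplitude jitter", {
  arr <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  r <- roi_disk(3, 3, c(2, 2), 1.5)
  same <- trial_variability(list(arr, arr, arr), r)
  expect_equal(same$dispersion, rep(0, 8))
  expect_error(trial_variability(list(), r), "empty")

  # generator amplitude jitter reappears as peak-amplitude sd (noise off so
  # the jitter is the only across-trial variance source)
  cfg <- synth_config(H = 6, W = 6, n_frames = 110, onset_frame = 11,
                      n_conditions = 1, trials_per_condition = 40,
                      n_blanks = 0, response_amplitudes = 0.004,
                      amplitude_jitter_sd = 0.2, noise_sd = 0,
                      heartbeat_amplitude = 0, bleach_amplitude = 0,
                      roi_radius = 3, seed = 31)
  ses <- generate_session(cfg)
  amps <- ses$truth$schedule$amplitude
  expect_equal(sd(amps) / mean(amps), 0.2, tolerance = 0.35)
  r2 <- roi_disk(6, 6, cfg$roi_center, 2)
  tv <- trial_variability(lapply(ses$trials, function(x)
    frames0_divide(x)$data - 1), r2)
  peak_frame <- which.max(rowMeans(tv$timecourses))
  peak_sd <- sd(tv$timecourses[peak_frame, ])
  sigma_c <- sd(amps) * mean(tv$timecourses[peak_frame, ]) / mean(amps)
  expect_lt(abs(peak_sd - sigma_c), 3 * sigma_c / sqrt(2 * (40 - 1)))

  # plot artifact
  pf <- file.path(withr::local_tempdir(), "var.png")
  trial_variability(list(arr, arr + 1), r, plot_file = pf)
  expect_true(file.exists(pf))
})

test_that("method comparison pairs timecourses and reports RMS difference", {
  arr <- array(rnorm(3 * 3 * 10), c(3, 3, 10))
  r <- roi_disk(3, 3, c(2, 2), 1.5)
  self <- compare_methods(list(arr), list(arr), r)
  expect_equal(self$rms_difference, 0)

  shifted <- compare_methods(list(arr), list(arr + 0.3), r)
  expect_equal(shifted$rms_difference, 0.3, tolerance = 1e-12)
  expect_equal(shifted$difference, rep(-0.3, 10), tolerance = 1e-12)

  expect_error(compare_methods(list(arr), list(arr, arr), r), "same")
})

test_that("the heartbeat map is the fractional harmonic amplitude", {
  # constructed fit: beta_sin = 3, beta_cos = 4, beta0 = 10 -> 5/10 = 0.5
  labels <- c("constant", "sin_f2.5_h1", "cos_f2.5_h1")
  beta <- array(0, c(2, 2, 3), dimnames = list(NULL, NULL, labels))
  beta[, , 1] <- 10; beta[, , 2] <- 3; beta[, , 3] <- 4
  design <- structure(list(X = matrix(0, 4, 3), labels = labels,
                           partition = list(constant = 1L, noise = 2:3,
                                            signal = integer(0)),
                           t_grid = (0:3) / 110, onset_frame = 1L,
                           sampling_rate = 110,
                           info = list(tau = NULL, frequencies = 2.5,
                                       n_harmonics = 1L)),
                      class = "vsdi_design")
  fake <- structure(list(beta = beta, design = design), class = "vsdi_fit")
  expect_equal(heartbeat_contribution_map(fake),
               matrix(0.5, 2, 2))

  # no heartbeat columns: error
  design2 <- design; design2$info$frequencies <- numeric(0)
  fake2 <- fake; fake2$design <- design2
  expect_error(heartbeat_contribution_map(fake2), "no heartbeat")
})

test_that("the heartbeat map recovers the generated amplitude, phase-free", {
  ses <- tiny_session()
  cf <- ses$truth$config
  des <- study_design(ses, L = 4)
  fits <- lapply(stim_index(ses), function(k) fit_glm(ses$trials[[k]], des))
  hb <- heartbeat_contribution_map(fits)
  r <- roi_disk(cf$H, cf$W, cf$roi_center, 3)
  expect_lt(abs(mean(hb[r$mask]) - cf$heartbeat_amplitude),
            0.15 * cf$heartbeat_amplitude)

  # amplitude, not phase, is mapped: a pi/3 phase shift leaves it unchanged
  k <- stim_index(ses)[1]
  tr <- ses$trials[[k]]
  t <- (seq_len(dim(tr$data)[3]) - 1) / cf$sampling_rate
  base <- ses$truth$baselines[[k]]
  hb_old <- ses$truth$noise_tc$heartbeat[, k]
  hb_new <- cf$heartbeat_amplitude *
    sin(2 * pi * cf$heartbeat_freq * t + ses$truth$schedule$heartbeat_phase[k] +
          pi / 3)
  shift <- outer(as.vector(base), hb_new - hb_old)
  dim(shift) <- dim(tr$data)
  tr2 <- trial_stack(tr$data + shift, tr$sampling_rate, tr$onset_frame,
                     tr$meta)
  m1 <- heartbeat_contribution_map(fit_glm(tr, des))
  m2 <- heartbeat_contribution_map(fit_glm(tr2, des))
  expect_equal(mean(m2[r$mask]), mean(m1[r$mask]), tolerance = 0.05)
})

test_that("condition reports write tables and a figure", {
  ses <- tiny_session()
  des <- study_design(ses, L = 3)
  sched <- ses$truth$schedule
  stim <- stim_index(ses)
  dffs <- lapply(stim, function(k) fit_glm(ses$trials[[k]], des)$dff)
  r <- roi_disk(8, 8, c(4.5, 4.5), 3)
  dir <- withr::local_tempdir()
  rows <- write_condition_report(dffs, sched$condition[stim], r, 110, dir)
  expect_true(file.exists(file.path(dir, "conditions_cond01.tsv")))
  expect_true(file.exists(file.path(dir, "conditions_cond02.tsv")))
  expect_true(file.exists(file.path(dir, "conditions.png")))
  tab <- read.delim(file.path(dir, "conditions_cond01.tsv"))
  expect_equal(nrow(tab), 110)
  expect_equal(unique(tab$n), 2)
  # aggregation is permutation-invariant over trials
  rows2 <- write_condition_report(rev(dffs), rev(sched$condition[stim]), r,
                                  110, withr::local_tempdir())
  expect_equal(rows$mean, rows2$mean, tolerance = 1e-12)
})
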