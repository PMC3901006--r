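# Seeded synthetic-session generator. Emulates a heartbeat-triggered
# trial-based optical-imaging session: a smooth positive baseline image
# modulated multiplicatively by dye bleaching (decaying exponential),
# near-phase-locked heartbeat oscillation, optional extra oscillations, a
# localized evoked response c * A(x,y) * r(t - onset), and i.i.d. Gaussian
# broadband noise. Every fractional component scales the baseline, which is
# the regime in which frames-0 division and baseline-coefficient
# normalization are exact, so ground-truth recovery tests are interpretable.

#' Synthetic-session configuration
#'
#' Defaults mirror a single-condition-series awake-primate dye-imaging
#' session recorded at 110 Hz: 6 stimulus conditions x 10 trials plus 20
#' blank trials (80 trials), 220 frames per trial with a 0.2 s pre-stimulus
#' window, 3% bleaching with a 2 s time constant, a 2.5 Hz heartbeat at 0.2%
#' of baseline with small phase jitter (acquisition is heartbeat-triggered),
#' evoked peak amplitudes of 0.1-0.6% dF/F across conditions, and 0.1%
#' per-pixel broadband noise. Image size defaults to 16 x 16 for tractable
#' simulation studies.
#'
#' @param H,W,n_frames stack dimensions.
#' @param sampling_rate Hz.
#' @param onset_frame 0-based stimulus onset frame (>= 1).
#' @param n_conditions,trials_per_condition,n_blanks session structure;
#'   `n_conditions` may be 0 for a blanks-only session.
#' @param baseline_mean mean baseline fluorescence, arbitrary units.
#' @param baseline_spatial_cv coefficient of variation of the baseline field.
#' @param bleach_amplitude,bleach_tau fractional bleaching amplitude and its
#'   time constant in seconds.
#' @param heartbeat_freq,heartbeat_amplitude Hz and fraction of baseline.
#' @param heartbeat_phase_jitter sd (radians) of the per-trial heartbeat
#'   phase around 0.
#' @param extra_oscillations list of `c(freq_hz, amplitude_fraction)` pairs
#'   with uniform random phase per trial.
#' @param response_amplitudes numeric vector, one peak dF/F fraction per
#'   condition.
#' @param amplitude_jitter_sd per-trial multiplicative response-amplitude
#'   jitter sd (fraction; default 0).
#' @param shape true response shape, a [shape_params()].
#' @param roi_center `c(row, col)` of the response bump (1-based pixels).
#' @param roi_radius bump radius in pixels (response is 1 at the center and
#'   0 at and beyond the radius).
#' @param noise_sd per-pixel per-frame Gaussian noise sd as a fraction of
#'   the local baseline.
#' @param seed integer master seed; all per-trial randomness derives from it
#'   through fixed substream offsets.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(H = 16, W = 16, n_frames = 220, sampling_rate = 110,
                         onset_frame = 22, n_conditions = 6,
                         trials_per_condition = 10, n_blanks = 20,
                         baseline_mean = 1000, baseline_spatial_cv = 0.1,
                         bleach_amplitude = 0.03, bleach_tau = 2,
                         heartbeat_freq = 2.5, heartbeat_amplitude = 0.002,
                         heartbeat_phase_jitter = 0.1,
                         extra_oscillations = list(),
                         response_amplitudes = c(1, 2, 3, 4, 5, 6) / 1000,
                         amplitude_jitter_sd = 0,
                         shape = shape_params(),
                         roi_center = NULL, roi_radius = 5,
                         noise_sd = 0.001, seed = 42L) {
  if (is.null(roi_center)) roi_center <- c((H + 1) / 2, (W + 1) / 2)
  cfg <- list(H = as.integer(H), W = as.integer(W),
              n_frames = as.integer(n_frames),
              sampling_rate = sampling_rate,
              onset_frame = as.integer(onset_frame),
              n_conditions = as.integer(n_conditions),
              trials_per_condition = as.integer(trials_per_condition),
              n_blanks = as.integer(n_blanks),
              baseline_mean = baseline_mean,
              baseline_spatial_cv = baseline_spatial_cv,
              bleach_amplitude = bleach_amplitude, bleach_tau = bleach_tau,
              heartbeat_freq = heartbeat_freq,
              heartbeat_amplitude = heartbeat_amplitude,
              heartbeat_phase_jitter = heartbeat_phase_jitter,
              extra_oscillations = extra_oscillations,
              response_amplitudes = as.numeric(response_amplitudes),
              amplitude_jitter_sd = amplitude_jitter_sd,
              shape = shape,
              roi_center = roi_center, roi_radius = roi_radius,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (H < 1 || W < 1 || n_frames < 2) stop("invalid dimensions")
    if (onset_frame < 1 || onset_frame >= n_frames)
      stop("onset_frame must satisfy 1 <= onset_frame < n_frames")
    if (bleach_tau <= 0) stop("bleach_tau must be > 0")
    if (heartbeat_freq >= sampling_rate / 2)
      stop("heartbeat_freq must be below Nyquist")
    if (noise_sd < 0 || bleach_amplitude < 0 || heartbeat_amplitude < 0 ||
        any(response_amplitudes < 0) || amplitude_jitter_sd < 0)
      stop("amplitudes and noise_sd must be >= 0")
    if (length(response_amplitudes) != n_conditions)
      stop("response_amplitudes must have exactly n_conditions entries")
    if (baseline_mean <= 0 || baseline_spatial_cv < 0)
      stop("invalid baseline parameters")
  })
  invisible(cfg)
}

# Deterministic substream seeds; offsets are fixed primes so trial k is
# reproducible in isolation. Kept below 2^31 - 1.
substream_seed <- function(seed, k) as.integer((seed + 7919 * k) %% 2147483629L)

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k / sum(k)
}

smooth1d <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))  # edge replication
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1L):(half + length(x))])
}

gauss_smooth2d <- function(mat, sigma) {
  k <- gaussian_kernel(sigma)
  mat <- apply(mat, 2L, smooth1d, k = k)
  t(apply(mat, 1L, smooth1d, k = k))
}

# Smooth positive baseline field with target mean and coefficient of
# variation, built by Gaussian-smoothing white noise then affine rescaling.
baseline_field <- function(H, W, mean, cv) {
  z <- matrix(stats::rnorm(H * W), H, W)
  z <- gauss_smooth2d(z, sigma = max(1, max(H, W) / 8))
  if (cv > 0 && stats::sd(z) > 0) z <- (z - base::mean(z)) / stats::sd(z) * cv
  else z <- z * 0
  F0 <- mean * (1 + z)
  if (any(F0 <= 0))
    stop("baseline field non-positive; reduce baseline_spatial_cv")
  F0
}

# Radial raised-cosine bump: 1 at the center, 0 at and beyond the radius.
response_profile <- function(H, W, center, radius) {
  d <- sqrt(outer((seq_len(H) - center[1])^2, (seq_len(W) - center[2])^2, `+`))
  A <- 0.5 * (1 + cos(pi * pmin(d / radius, 1)))
  A[d >= radius] <- 0
  A
}

#' Generate a synthetic imaging session with ground truth
#'
#' Draws the full session described by a [synth_config()]: a randomized
#' trial schedule interleaving blank (condition 0) and stimulated trials,
#' and for each trial a movie
#' `F = F0(x,y) * (1 + bleach(t) + heartbeat(t) + extras(t) + c * A(x,y) * r(t - onset)) + F0 * noise_sd * eta`.
#' Fully deterministic given the config seed; trial k draws from a fixed
#' substream so it is reproducible in isolation.
#'
#' @param config a [synth_config()].
#' @param session_date,experiment_number metadata stamped on every trial.
#' @return List with `trials` (list of [trial_stack()]) and `truth`, a
#'   `synth_truth` list: `profile` (H x W response profile A), `schedule`
#'   (data frame: trial number, condition, drawn amplitude, heartbeat
#'   phase), `baselines` (per-trial H x W fields), `response_tc`
#'   (T x n_trials matrix of true fractional response timecourses at
#'   profile = 1), `noise_tc` (list with `bleach` vector and `heartbeat`
#'   T x n_trials matrix), and the `config`.
#' @export
generate_session <- function(config, session_date = "2026-01-15",
                             experiment_number = 1L) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  n_stim <- cf$n_conditions * cf$trials_per_condition
  n_total <- n_stim + cf$n_blanks
  if (n_total < 1L) stop("empty session")
  codes <- c(rep.int(0L, cf$n_blanks),
             rep(seq_len(cf$n_conditions), each = cf$trials_per_condition))
  set.seed(substream_seed(cf$seed, 0L))
  codes <- sample(codes)

  t_all <- (seq_len(cf$n_frames) - 1) / cf$sampling_rate
  n_post <- cf$n_frames - cf$onset_frame
  t_post <- (seq_len(n_post) - 1) / cf$sampling_rate
  r_post <- response_shape(t_post, cf$shape)
  r_full <- c(rep(0, cf$onset_frame), r_post)
  bleach_tc <- cf$bleach_amplitude * exp(-t_all / cf$bleach_tau)
  A <- response_profile(cf$H, cf$W, cf$roi_center, cf$roi_radius)

  trials <- vector("list", n_total)
  baselines <- vector("list", n_total)
  response_tc <- matrix(0, cf$n_frames, n_total)
  heartbeat_tc <- matrix(0, cf$n_frames, n_total)
  amp_drawn <- numeric(n_total)
  phase_drawn <- numeric(n_total)

  for (k in seq_len(n_total)) {
    set.seed(substream_seed(cf$seed, k))
    F0 <- baseline_field(cf$H, cf$W, cf$baseline_mean, cf$baseline_spatial_cv)
    phi <- stats::rnorm(1, 0, cf$heartbeat_phase_jitter)
    hb <- cf$heartbeat_amplitude * sin(2 * pi * cf$heartbeat_freq * t_all + phi)
    common <- bleach_tc + hb
    for (osc in cf$extra_oscillations) {
      common <- common + osc[2] * sin(2 * pi * osc[1] * t_all +
                                        stats::runif(1, 0, 2 * pi))
    }
    code <- codes[k]
    c_k <- 0
    if (code > 0L) {
      c_k <- cf$response_amplitudes[code]
      if (cf$amplitude_jitter_sd > 0)
        c_k <- c_k * (1 + stats::rnorm(1, 0, cf$amplitude_jitter_sd))
    }
    resp <- c_k * r_full
    frac_min <- min(common) + min(0, min(resp))  # A in [0,1]
    if (1 + frac_min <= 0)
      stop("generated intensities would be non-positive; ",
           "reduce component amplitudes")
    # data[h, w, t] = F0 * (1 + common[t] + A * resp[t]) + F0 * sd * eta
    arr <- outer(F0, 1 + common) + outer(A * F0, resp)
    if (cf$noise_sd > 0)
      arr <- arr + as.vector(F0) * cf$noise_sd *
        stats::rnorm(cf$H * cf$W * cf$n_frames)
    dim(arr) <- c(cf$H, cf$W, cf$n_frames)
    meta <- trial_meta(session_date, experiment_number, k, code)
    trials[[k]] <- trial_stack(arr, cf$sampling_rate, cf$onset_frame, meta)
    baselines[[k]] <- F0
    response_tc[, k] <- resp
    heartbeat_tc[, k] <- hb
    amp_drawn[k] <- c_k
    phase_drawn[k] <- phi
  }

  truth <- structure(list(
    profile = A,
    schedule = data.frame(trial_number = seq_len(n_total), condition = codes,
                          amplitude = amp_drawn, heartbeat_phase = phase_drawn),
    baselines = baselines,
    response_tc = response_tc,
    noise_tc = list(bleach = bleach_tc, heartbeat = heartbeat_tc),
    config = cf), class = "synth_truth")
  list(trials = trials, truth = truth)
}

#' Write a generated session to disk
#'
#' Writes every trial as a NIfTI file under the naming convention, builds
#' the condition table, and stores the ground truth as plain text/NIfTI:
#' the response profile as NIfTI, the schedule and true timecourses as TSV.
#'
#' @param session result of [generate_session()].
#' @param dir output directory (created if needed).
#' @return The [build_condition_table()] index, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in session$trials) write_stack(tr, dir)
  idx <- build_condition_table(dir)
  truth <- session$truth
  prof <- truth$profile
  dim(prof) <- c(dim(prof), 1L)
  RNifti::writeNifti(RNifti::asNifti(aperm(prof, c(2, 1, 3))),
                     file.path(dir, "truth_profile.nii.gz"))
  utils::write.table(truth$schedule, file.path(dir, "truth_schedule.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tc <- data.frame(frame = seq_len(nrow(truth$response_tc)) - 1L,
                   truth$response_tc)
  names(tc) <- c("frame", sprintf("trial%04d", seq_len(ncol(truth$response_tc))))
  utils::write.table(tc, file.path(dir, "truth_response_tc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(idx)
}
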