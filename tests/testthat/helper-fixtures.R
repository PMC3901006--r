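# Shared fixtures. Sessions are generated once per test run and cached;
# everything is built in code (no stored binaries).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small fast session used by most module tests.
tiny_config <- function(...) {
  args <- list(H = 8, W = 8, n_frames = 110, sampling_rate = 110,
               onset_frame = 11, n_conditions = 2, trials_per_condition = 2,
               n_blanks = 3, response_amplitudes = c(0.002, 0.004),
               roi_radius = 3, seed = 101)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

tiny_session <- function() cached("tiny", generate_session(tiny_config()))

# Study-scale session mirroring the distributed-dataset design:
# 16x16x220 @ 110 Hz, 6 conditions x 10 trials + 20 blanks.
default_session <- function() cached("default",
                                     generate_session(synth_config(seed = 7)))

# Noise-component-free session (noise sd, bleaching, heartbeat all off) for
# exact-recovery oracles.
noiseless_config <- function(...) {
  args <- list(noise_sd = 0, bleach_amplitude = 0, heartbeat_amplitude = 0,
               heartbeat_phase_jitter = 0, n_conditions = 2,
               trials_per_condition = 2, n_blanks = 2,
               response_amplitudes = c(0.002, 0.004), seed = 5)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

noiseless_session <- function() cached("noiseless",
                                       generate_session(noiseless_config()))

# Study sweep intervals around the generator's shape prototype; L chosen so
# the prototype reconstructs to < 1% max error (see the methods vignette).
study_intervals <- function() {
  shape_intervals(latency = c(0, 0.1, 3), rise = c(0.2, 0.4, 3),
                  plateau = c(0.4, 0.8, 3), decay = c(0.3, 0.5, 3))
}
study_L <- 15L

blanks_of <- function(session) {
  session$trials[vapply(session$trials, function(x) is_blank(x$meta),
                        logical(1))]
}

stim_index <- function(session) which(session$truth$schedule$condition != 0)

mean_blank_timecourse <- function(session) {
  blanks <- blanks_of(session)
  n <- dim(blanks[[1]]$data)[3]
  rowMeans(vapply(blanks, function(b) apply(b$data, 3L, mean), numeric(n)))
}

# Design matrix for a session, with noise parameters estimated from its
# blanks (the standard workflow).
study_design <- function(session, L = study_L, n_harmonics = 2L) {
  cf <- session$truth$config
  est <- estimate_tau_and_heartbeat(mean_blank_timecourse(session),
                                    cf$sampling_rate)
  sb <- make_signal_block(study_intervals(), cf$n_frames, cf$sampling_rate,
                          cf$onset_frame, L = L)
  build_design_matrix(cf$n_frames, cf$sampling_rate, cf$onset_frame,
                      noise_spec(tau = est$tau,
                                 oscillation_freqs = est$f_heart,
                                 n_harmonics = n_harmonics),
                      shape_basis = sb)
}

# Random valid shape parameters: positive durations for every segment whose
# depth is nonzero, so the curve is continuous.
random_shape_params <- function() {
  shape_params(latency = runif(1, 0, 0.3), dip = runif(1, 0.05, 0.3),
               rise = runif(1, 0.05, 0.5), plateau = runif(1, 0, 0.6),
               decay = runif(1, 0.05, 0.5), undershoot = runif(1, 0.05, 0.4),
               dip_depth = runif(1), undershoot_depth = runif(1))
}

random_meta <- function(k = 1L, cond = 1L) {
  trial_meta("2026-01-15", 1L, k, cond)
}

random_stack <- function(H = 4, W = 5, T = 12, onset = 3, k = 1L, cond = 1L) {
  trial_stack(array(runif(H * W * T, 90, 110), c(H, W, T)),
              sampling_rate = 110, onset_frame = onset,
              meta = random_meta(k, cond))
}

# Wrap an arbitrary full-rank matrix (first column constant) as a design
# object, for oracle comparisons that bypass build_design_matrix.
make_design_from_matrix <- function(X, labels = colnames(X),
                                    noise_idx = integer(0),
                                    signal_idx = integer(0), fs = 110) {
  structure(list(X = X, labels = labels,
                 partition = list(constant = 1L, noise = noise_idx,
                                  signal = signal_idx),
                 t_grid = (seq_len(nrow(X)) - 1) / fs,
                 onset_frame = 1L, sampling_rate = fs,
                 info = list(tau = NULL, frequencies = numeric(0),
                             n_harmonics = 1L)),
            class = "vsdi_design")
}
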