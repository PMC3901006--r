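# Design-matrix construction: the parametric response-shape family and its
# PCA basis (signal block Xs), and the noise block Xn (dye-bleaching
# exponential + heartbeat/oscillation Fourier series) with data-driven
# parameter estimation from blank trials.

#' Parameters of the piecewise-cosine response-shape model
#'
#' The canonical evoked-response shape r(t) is a continuous piecewise
#' half-cosine curve parameterized by six durations (seconds) and two
#' depths (dimensionless fractions of the plateau height):
#' latency (`latency`), initial dip of depth `dip_depth` over `dip`,
#' rise to the plateau over `rise`, plateau of length `plateau` at height 1,
#' decay to an undershoot of depth `undershoot_depth` over `decay`, and
#' recovery back to 0 over `undershoot`. Segments with zero duration are
#' skipped; a segment leading to a nonzero depth should have nonzero
#' duration, otherwise the curve jumps there.
#'
#' @param latency,dip,rise,plateau,decay,undershoot segment durations, s >= 0.
#' @param dip_depth,undershoot_depth depths in `[0, 1]`.
#' @return An object of class `shape_params` (numeric vector of length 8).
#' @export
shape_params <- function(latency = 0.05, dip = 0, rise = 0.3, plateau = 0.6,
                         decay = 0.4, undershoot = 0, dip_depth = 0,
                         undershoot_depth = 0) {
  p <- as.numeric(c(latency, dip, rise, plateau, decay, undershoot,
                    dip_depth, undershoot_depth))
  names(p) <- c("latency", "dip", "rise", "plateau", "decay", "undershoot",
                "dip_depth", "undershoot_depth")
  if (length(p) != 8L) stop("each shape parameter must be a scalar")
  if (any(!is.finite(p))) stop("non-finite shape parameter")
  if (any(p[1:6] < 0)) stop("durations must be >= 0")
  if (p["dip_depth"] < 0 || p["dip_depth"] > 1 ||
      p["undershoot_depth"] < 0 || p["undershoot_depth"] > 1)
    stop("depths must lie in [0, 1]")
  structure(p, class = "shape_params")
}

#' Evaluate the response-shape model
#'
#' Evaluates r(t) on a time grid. With s = t - latency and cumulative
#' breakpoints over (dip, rise, plateau, decay, undershoot):
#' r = 0 for s <= 0; a half-cosine dip to `-dip_depth`; a half-cosine rise
#' from `-dip_depth` to 1; a plateau at 1; a half-cosine fall from 1 to
#' `-undershoot_depth`; a half-cosine recovery to 0; and 0 afterwards.
#' Cosine coefficients are fixed by continuity at every breakpoint.
#'
#' @param t_grid numeric vector of times in seconds.
#' @param p a [shape_params()] object.
#' @return Numeric vector of r(t) values, dimensionless, in
#'   `[-max(depths), 1]`.
#' @export
response_shape <- function(t_grid, p) {
  if (!inherits(p, "shape_params")) p <- do.call(shape_params, as.list(p))
  a1 <- p[[1]]; a2 <- p[[2]]; a3 <- p[[3]]; a4 <- p[[4]]
  a5 <- p[[5]]; a6 <- p[[6]]; a7 <- p[[7]]; a8 <- p[[8]]
  s <- t_grid - a1
  b <- cumsum(c(a2, a3, a4, a5, a6))  # segment end offsets
  r <- numeric(length(s))
  if (a2 > 0) {
    i <- s > 0 & s <= b[1]
    r[i] <- (a7 / 2) * (cos(pi * s[i] / a2) - 1)
  }
  if (a3 > 0) {
    i <- s > b[1] & s <= b[2]
    r[i] <- (1 - a7) / 2 - ((1 + a7) / 2) * cos(pi * (s[i] - b[1]) / a3)
  }
  if (a4 > 0) {
    i <- s > b[2] & s <= b[3]
    r[i] <- 1
  }
  if (a5 > 0) {
    i <- s > b[3] & s <= b[4]
    r[i] <- (1 - a8) / 2 + ((1 + a8) / 2) * cos(pi * (s[i] - b[3]) / a5)
  }
  if (a6 > 0) {
    i <- s > b[4] & s <= b[5]
    r[i] <- -(a8 / 2) * (1 + cos(pi * (s[i] - b[4]) / a6))
  }
  r
}

#' Sweep ranges for the shape parameters
#'
#' For each of the eight shape parameters, a (min, max, n_steps) triple.
#' The shape library enumerates the Cartesian product of
#' `seq(min, max, length.out = n_steps)` over all parameters
#' (`n_steps = 1` uses the interval midpoint).
#'
#' @param ... named triples, e.g. `rise = c(0.2, 0.4, 3)`. Unnamed
#'   parameters default to a single step at the [shape_params()] default.
#' @param cap maximum admissible library size (guards the full sweep).
#' @return An object of class `shape_intervals`.
#' @export
shape_intervals <- function(..., cap = 1e5) {
  defaults <- unclass(shape_params())
  iv <- lapply(names(defaults), function(nm) c(defaults[[nm]], defaults[[nm]], 1))
  names(iv) <- names(defaults)
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    stop("all interval arguments must be named")
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) stop("unknown shape parameter: ", nm)
    v <- user[[nm]]
    if (length(v) == 2L) v <- c(v, 3)  # default 3 steps when swept
    if (length(v) != 3L || v[1] > v[2] || v[3] < 1 || v[3] != round(v[3]))
      stop("interval for ", nm, " must be (min, max, n_steps >= 1)")
    iv[[nm]] <- v
  }
  n <- prod(vapply(iv, `[`, numeric(1), 3))
  if (n > cap)
    stop("shape library would hold ", n, " shapes, exceeding the cap of ", cap)
  structure(list(intervals = iv, cap = cap), class = "shape_intervals")
}

interval_values <- function(triple) {
  if (triple[3] == 1) (triple[1] + triple[2]) / 2
  else seq(triple[1], triple[2], length.out = triple[3])
}

#' Enumerate the shape library
#'
#' Evaluates [response_shape()] for every combination of swept parameter
#' values, one row per combination, in deterministic lexicographic order
#' (last parameter varying fastest). All-zero shapes (degenerate
#' combinations) are dropped with a message.
#'
#' @param intervals a [shape_intervals()].
#' @param t_grid time grid in seconds (typically the post-onset grid).
#' @return `n_shapes x length(t_grid)` matrix; attribute `"params"` holds the
#'   parameter combination per row.
#' @export
generate_shape_library <- function(intervals, t_grid) {
  stopifnot(inherits(intervals, "shape_intervals"))
  vals <- lapply(intervals$intervals, interval_values)
  grid <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(vals)), drop = FALSE]  # lexicographic order
  lib <- t(apply(grid, 1L, function(row)
    response_shape(t_grid, shape_params(row[1], row[2], row[3], row[4],
                                        row[5], row[6], row[7], row[8]))))
  if (length(t_grid) == 1L) lib <- matrix(lib, ncol = 1L)
  keep <- rowSums(abs(lib)) > 0
  if (!all(keep))
    message("dropping ", sum(!keep), " degenerate all-zero shape(s)")
  structure(lib[keep, , drop = FALSE], params = grid[keep, , drop = FALSE])
}

#' PCA signal basis from a shape library
#'
#' Reduces the shape library to an orthonormal basis of its first `L`
#' principal directions (uncentered singular value decomposition by default,
#' so the constant component of the shapes stays in the signal block rather
#' than leaking into the baseline regressor). Column signs are fixed so each
#' component's largest-magnitude entry is positive.
#'
#' @param library `n_shapes x T` matrix from [generate_shape_library()].
#' @param L number of components, `1 <= L <= min(n_shapes, T)`; `NULL`
#'   selects the smallest L capturing at least `energy` of the total
#'   squared singular values.
#' @param energy energy fraction used when `L` is `NULL` (default 0.99).
#' @param center mean-center the library before decomposition (default
#'   `FALSE`; see Details in the vignette).
#' @return `T x L` matrix with orthonormal columns, ordered by decreasing
#'   singular value; attribute `"singular_values"`.
#' @export
shape_basis <- function(library, L = NULL, energy = 0.99, center = FALSE) {
  if (!is.matrix(library) || nrow(library) < 1L)
    stop("library must be a non-empty matrix")
  M <- if (center) sweep(library, 2L, colMeans(library)) else library
  sv <- svd(M)
  if (is.null(L)) {
    cum <- cumsum(sv$d^2) / sum(sv$d^2)
    L <- which(cum >= energy)[1]
  }
  if (L < 1L || L > min(dim(library)))
    stop("L must lie in [1, ", min(dim(library)), "]")
  V <- sv$v[, seq_len(L), drop = FALSE]
  for (j in seq_len(L)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(V, singular_values = sv$d)
}

#' Noise-regressor specification
#'
#' Declares the noise block of the design matrix: an optional dye-bleaching
#' exponential `exp(-t/tau)` and sine/cosine pairs at the listed oscillation
#' frequencies. The first frequency is treated as the heartbeat and expanded
#' to `n_harmonics` harmonics; any further frequencies get a single pair.
#'
#' @param tau bleaching time constant in seconds (> 0), or `NULL` to omit
#'   the exponential.
#' @param oscillation_freqs numeric vector of frequencies in Hz; may be
#'   empty. First entry = heartbeat.
#' @param n_harmonics harmonics for the heartbeat frequency (default 2).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(tau = NULL, oscillation_freqs = numeric(0),
                       n_harmonics = 2L) {
  if (!is.null(tau) && (!is.numeric(tau) || tau <= 0))
    stop("tau must be > 0 seconds")
  if (any(oscillation_freqs <= 0)) stop("frequencies must be positive")
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  structure(list(tau = tau,
                 oscillation_freqs = as.numeric(oscillation_freqs),
                 n_harmonics = as.integer(n_harmonics)),
            class = "noise_spec")
}

amplitude_spectrum <- function(y) {
  n <- length(y)
  a <- Mod(stats::fft(y))[seq_len(n %/% 2 + 1)] / n
  a
}

#' Estimate the bleaching time constant and heartbeat frequency
#'
#' Fits `constant + b * exp(-t/tau)` to a (typically spatially averaged
#' blank) timecourse by least squares over a grid of candidate tau values and
#' keeps the minimizer; then locates the strongest periodogram ordinate of
#' the exponential-removed residual within the heart band. Ties in the
#' periodogram break toward the lower frequency.
#'
#' @param timecourse numeric vector, length >= 16.
#' @param sampling_rate Hz.
#' @param tau_grid candidate tau values in seconds; default 50 log-spaced
#'   values spanning 0.1x to 10x the trial duration.
#' @param heart_band numeric `(low, high)` Hz; clipped to (0, Nyquist).
#' @return List with `tau`, `f_heart` (Hz; `NA` with a warning when the
#'   residual spectrum is flat), `tau_rss` and `residual`.
#' @export
estimate_tau_and_heartbeat <- function(timecourse, sampling_rate,
                                       tau_grid = NULL,
                                       heart_band = c(0.5, 15)) {
  n <- length(timecourse)
  if (n < 16L) stop("timecourse too short (need >= 16 samples)")
  t <- (seq_len(n) - 1) / sampling_rate
  dur <- n / sampling_rate
  if (is.null(tau_grid))
    tau_grid <- exp(seq(log(0.1 * dur), log(10 * dur), length.out = 50))
  rss <- vapply(tau_grid, function(tau) {
    X <- cbind(1, exp(-t / tau))
    sum(stats::lm.fit(X, timecourse)$residuals^2)
  }, numeric(1))
  tau <- tau_grid[which.min(rss)]
  fit <- stats::lm.fit(cbind(1, exp(-t / tau)), timecourse)
  resid <- fit$residuals
  nyq <- sampling_rate / 2
  band <- c(max(heart_band[1], 0), min(heart_band[2], nyq))
  if (band[1] >= band[2]) stop("heart band empty after Nyquist clipping")
  a <- amplitude_spectrum(resid)
  freqs <- (seq_along(a) - 1) * sampling_rate / n
  in_band <- freqs > band[1] & freqs <= band[2] & freqs > 0
  if (!any(in_band)) stop("no spectral ordinate inside the heart band")
  f_heart <- NA_real_
  if (max(a[in_band]) <= 1e-12 * max(a[1], stats::sd(timecourse), 1e-300)) {
    warning("no oscillation found in the heart band (flat spectrum)")
  } else {
    cand <- which(in_band)
    best <- cand[a[cand] == max(a[cand])]   # ties -> lower frequency
    f_heart <- freqs[min(best)]
  }
  list(tau = tau, f_heart = f_heart, tau_rss = min(rss), residual = resid)
}

#' Detect oscillatory noise peaks in a blank timecourse spectrum
#'
#' Flags local maxima of the amplitude spectrum exceeding
#' `median + z_threshold * MAD` (median/MAD over the full non-DC spectrum),
#' excluding DC, user-excluded bands, and ordinates within one resolution
#' bin (`sampling_rate/T`) of an already-accepted stronger peak. Returned
#' sorted by descending amplitude.
#'
#' @param timecourse numeric vector.
#' @param sampling_rate Hz.
#' @param z_threshold robust z threshold (default 8).
#' @param exclude_bands list of `(low, high)` Hz intervals to ignore.
#' @return Numeric vector of peak frequencies in Hz (possibly empty), with
#'   attribute `"amplitudes"`.
#' @export
spectral_peaks <- function(timecourse, sampling_rate, z_threshold = 8,
                           exclude_bands = list()) {
  n <- length(timecourse)
  a <- amplitude_spectrum(timecourse - mean(timecourse))
  freqs <- (seq_along(a) - 1) * sampling_rate / n
  df <- sampling_rate / n
  ok <- freqs > 0
  for (b in exclude_bands) ok <- ok & !(freqs >= b[1] & freqs <= b[2])
  thr <- stats::median(a[freqs > 0]) + z_threshold * stats::mad(a[freqs > 0])
  # local maxima among interior ordinates
  k <- seq(2L, length(a) - 1L)
  is_max <- logical(length(a))
  is_max[k] <- a[k] > a[k - 1L] & a[k] >= a[k + 1L]
  cand <- which(is_max & ok & a > thr)
  cand <- cand[order(a[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(freqs[i] - freqs[accepted]) > df))
      accepted <- c(accepted, i)
  }
  structure(freqs[accepted], amplitudes = a[accepted])
}

#' Build the trial design matrix
#'
#' Assembles the T x P design matrix `X = [X0 | Xn | Xs]` in fixed column
#' order: the constant baseline regressor, then the bleaching exponential
#' (if enabled), then sine/cosine pairs per oscillation frequency and
#' harmonic, then the signal (shape-basis) columns. Construction fails on
#' rank deficiency, reporting the condition number, and on harmonics at or
#' above Nyquist.
#'
#' @param n_frames number of frames T.
#' @param sampling_rate Hz.
#' @param onset_frame 0-based stimulus onset frame (shape columns must be
#'   zero before it; checked when `shape_basis` is supplied pre-padded).
#' @param noise a [noise_spec()].
#' @param shape_basis `T x L` matrix of signal columns (already padded with
#'   zeros before the onset frame), or `NULL` for a noise-only model.
#' @return An object of class `vsdi_design`: list with `X`, `labels`,
#'   `partition` (`constant`, `noise`, `signal` column index sets), `t_grid`,
#'   and `info` (tau, frequencies, harmonics).
#' @export
build_design_matrix <- function(n_frames, sampling_rate, onset_frame,
                                noise = noise_spec(), shape_basis = NULL) {
  t <- (seq_len(n_frames) - 1) / sampling_rate
  nyq <- sampling_rate / 2
  cols <- list(constant = rep(1, n_frames))
  labels <- "constant"
  part <- list(constant = 1L, noise = integer(0), signal = integer(0))
  p <- 1L
  if (!is.null(noise$tau)) {
    p <- p + 1L
    cols[[length(cols) + 1L]] <- exp(-t / noise$tau)
    labels <- c(labels, sprintf("exp_tau%.4g", noise$tau))
    part$noise <- c(part$noise, p)
  }
  freqs <- noise$oscillation_freqs
  for (i in seq_along(freqs)) {
    nh <- if (i == 1L) noise$n_harmonics else 1L
    for (h in seq_len(nh)) {
      fh <- h * freqs[i]
      if (fh >= nyq)
        stop(sprintf("harmonic %d of %.4g Hz is at/above Nyquist (%.4g Hz)",
                     h, freqs[i], nyq))
      cols[[length(cols) + 1L]] <- sin(2 * pi * fh * t)
      cols[[length(cols) + 1L]] <- cos(2 * pi * fh * t)
      labels <- c(labels, sprintf("sin_f%.6g_h%d", freqs[i], h),
                  sprintf("cos_f%.6g_h%d", freqs[i], h))
      part$noise <- c(part$noise, p + 1L, p + 2L)
      p <- p + 2L
    }
  }
  if (!is.null(shape_basis)) {
    sb <- as.matrix(shape_basis)
    if (nrow(sb) != n_frames)
      stop("shape basis has ", nrow(sb), " rows, expected ", n_frames)
    for (j in seq_len(ncol(sb))) {
      p <- p + 1L
      cols[[length(cols) + 1L]] <- sb[, j]
      labels <- c(labels, sprintf("shape_pc%d", j))
      part$signal <- c(part$signal, p)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    kap <- tryCatch(kappa(X, exact = TRUE), error = function(e) NA_real_)
    stop("design matrix is rank deficient (rank ", qrX$rank, " of ", ncol(X),
         "); dependent columns: ", paste(bad, collapse = ", "),
         "; condition number ", format(kap))
  }
  structure(list(X = X, labels = labels, partition = part, t_grid = t,
                 onset_frame = as.integer(onset_frame),
                 sampling_rate = sampling_rate,
                 info = list(tau = noise$tau, frequencies = freqs,
                             n_harmonics = noise$n_harmonics)),
            class = "vsdi_design")
}

#' @export
print.vsdi_design <- function(x, ...) {
  cat(sprintf("<vsdi_design> %d frames x %d regressors (noise %d, signal %d)\n",
              nrow(x$X), ncol(x$X), length(x$partition$noise),
              length(x$partition$signal)))
  invisible(x)
}

#' Construct the signal block for a trial grid
#'
#' Convenience wrapper: enumerates the shape library on the post-onset time
#' grid, reduces it with [shape_basis()], and pads the components with zeros
#' before the onset frame so they enter the design aligned to the stimulus.
#'
#' @inheritParams build_design_matrix
#' @param intervals a [shape_intervals()].
#' @param L,energy,center passed to [shape_basis()].
#' @return `n_frames x L` matrix of padded signal regressors.
#' @export
make_signal_block <- function(intervals, n_frames, sampling_rate, onset_frame,
                              L = NULL, energy = 0.99, center = FALSE) {
  n_post <- n_frames - onset_frame
  if (n_post < 2L) stop("fewer than 2 post-onset frames")
  t_post <- (seq_len(n_post) - 1) / sampling_rate
  lib <- generate_shape_library(intervals, t_post)
  B <- shape_basis(lib, L = L, energy = energy, center = center)
  rbind(matrix(0, onset_frame, ncol(B)), B)
}

#' Serialize a design matrix for provenance
#'
#' Writes the regressor matrix as TSV (columns labelled) and a JSON sidecar
#' holding the partition, time grid parameters and noise-model settings.
#'
#' @param design a `vsdi_design`.
#' @param path_tsv,path_json output paths.
#' @return `path_tsv`, invisibly.
#' @export
write_design_matrix <- function(design, path_tsv,
                                path_json = sub("\\.tsv$", ".json", path_tsv)) {
  stopifnot(inherits(design, "vsdi_design"))
  utils::write.table(design$X, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hdr <- list(labels = design$labels, partition = design$partition,
              n_frames = nrow(design$X), sampling_rate = design$sampling_rate,
              onset_frame = design$onset_frame, info = design$info)
  jsonlite::write_json(hdr, path_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path_tsv)
}

#' @rdname write_design_matrix
#' @export
read_design_matrix <- function(path_tsv,
                               path_json = sub("\\.tsv$", ".json", path_tsv)) {
  X <- as.matrix(utils::read.table(path_tsv, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  hdr <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  part <- lapply(hdr$partition, as.integer)
  if (is.null(part$noise)) part$noise <- integer(0)
  if (is.null(part$signal)) part$signal <- integer(0)
  structure(list(X = X, labels = hdr$labels, partition = part,
                 t_grid = (seq_len(hdr$n_frames) - 1) / hdr$sampling_rate,
                 onset_frame = as.integer(hdr$onset_frame),
                 sampling_rate = hdr$sampling_rate,
                 info = list(tau = hdr$info$tau,
                             frequencies = as.numeric(hdr$info$frequencies),
                             n_harmonics = as.integer(hdr$info$n_harmonics))),
            class = "vsdi_design")
}
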