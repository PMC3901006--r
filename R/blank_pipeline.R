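# The standard blank-subtraction workflow: frames-0 division, blank
# averaging, frame-by-frame blank subtraction, linear detrending.

#' Fractional (dF/F-scale) stack
#'
#' A trial movie expressed as dimensionless ratios relative to the
#' pre-stimulus baseline. Same axis convention as [trial_stack()].
#'
#' @param data H x W x T numeric array.
#' @param sampling_rate Hz.
#' @param onset_frame 0-based onset frame.
#' @param meta a [trial_meta()] (provenance of the source trial).
#' @return An object of class `fractional_stack`.
#' @export
fractional_stack <- function(data, sampling_rate, onset_frame, meta = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  structure(list(data = data, sampling_rate = sampling_rate,
                 onset_frame = as.integer(onset_frame), meta = meta),
            class = "fractional_stack")
}

#' @export
dim.fractional_stack <- function(x) dim(x$data)

#' @export
print.fractional_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fractional_stack> %dx%dx%d @ %g Hz, onset frame %d\n",
              d[1], d[2], d[3], x$sampling_rate, x$onset_frame))
  invisible(x)
}

#' Frames-0 division
#'
#' Normalizes a trial to its pre-stimulus baseline: every pixel's timecourse
#' is divided by that pixel's mean over the pre-stimulus frames
#' (frames `[0, onset)`, the "frames 0"). After division the pre-stimulus
#' mean of every pixel is exactly 1.
#'
#' @param stack a [trial_stack()] (or `fractional_stack`).
#' @param mask_nonpositive if `TRUE`, pixels whose baseline mean is <= 0 are
#'   set to `NaN` instead of aborting (count reported via a warning).
#' @return A [fractional_stack()].
#' @export
frames0_divide <- function(stack, mask_nonpositive = FALSE) {
  d <- dim(stack$data)
  onset <- stack$onset_frame
  if (onset < 1L) stop("need at least one pre-stimulus frame")
  base <- stack$data[, , seq_len(onset), drop = FALSE]
  b <- rowMeans(base, dims = 2L)
  bad <- b <= 0
  if (any(bad)) {
    if (!mask_nonpositive)
      stop(sum(bad), " pixel(s) have non-positive baseline mean")
    warning(sum(bad), " pixel(s) with non-positive baseline masked as NaN")
    b[bad] <- NA_real_
  }
  out <- stack$data / as.vector(b)  # recycles b over frames
  out[is.na(out)] <- NaN
  fractional_stack(out, stack$sampling_rate, onset, stack$meta)
}

#' Average blank trials
#'
#' Pointwise arithmetic mean of fractional blank stacks, the session-level
#' reference subtracted from every stimulated trial.
#'
#' @param blanks non-empty list of `fractional_stack`s with identical
#'   dimensions.
#' @return A [fractional_stack()] (metadata taken from the first blank, with
#'   condition 0).
#' @export
average_blanks <- function(blanks) {
  if (length(blanks) == 0L) stop("no blank trials supplied")
  d <- dim(blanks[[1]]$data)
  acc <- array(0, d)
  for (b in blanks) {
    if (!identical(dim(b$data), d))
      stop("blank dimension mismatch: ", paste(dim(b$data), collapse = "x"),
           " vs ", paste(d, collapse = "x"))
    acc <- acc + b$data
  }
  fractional_stack(acc / length(blanks), blanks[[1]]$sampling_rate,
                   blanks[[1]]$onset_frame, blanks[[1]]$meta)
}

#' Frame-by-frame blank subtraction
#'
#' Subtracts the blank average from a fractional trial pointwise; the result
#' is a dF/F movie centered at 0.
#'
#' @param trial,blank_mean `fractional_stack`s with identical dimensions.
#' @return A [fractional_stack()].
#' @export
blank_subtract <- function(trial, blank_mean) {
  if (!identical(dim(trial$data), dim(blank_mean$data)))
    stop("trial/blank dimension mismatch")
  fractional_stack(trial$data - blank_mean$data, trial$sampling_rate,
                   trial$onset_frame, trial$meta)
}

#' Linear detrending anchored on the trial's two baseline windows
#'
#' Ensures the estimated response returns to baseline at the end of the
#' trial: per pixel, the unique line through
#' (mean pre-stimulus time, mean pre-stimulus value) and
#' (mean end-window time, mean end-window value) is subtracted, after which
#' both window means are exactly 0.
#'
#' @param stack a `fractional_stack`.
#' @param end_window number of trailing frames in the end window (default:
#'   the pre-stimulus length, `onset_frame`); must not overlap the
#'   pre-stimulus window.
#' @return A [fractional_stack()].
#' @export
linear_detrend <- function(stack, end_window = NULL) {
  d <- dim(stack$data)
  onset <- stack$onset_frame
  if (is.null(end_window)) end_window <- onset
  end_window <- as.integer(end_window)
  if (end_window < 1L) stop("end_window must be >= 1")
  if (d[3] - end_window < onset)
    stop("end window overlaps the pre-stimulus window")
  pre_idx <- seq_len(onset)
  end_idx <- (d[3] - end_window + 1L):d[3]
  t <- seq_len(d[3]) - 1
  m_pre <- rowMeans(stack$data[, , pre_idx, drop = FALSE], dims = 2L)
  m_end <- rowMeans(stack$data[, , end_idx, drop = FALSE], dims = 2L)
  t_pre <- mean(t[pre_idx]); t_end <- mean(t[end_idx])
  slope <- (m_end - m_pre) / (t_end - t_pre)
  # line(t) = m_pre + slope * (t - t_pre), broadcast over frames
  npix <- d[1] * d[2]
  line <- rep(as.vector(m_pre), times = d[3]) +
    rep(as.vector(slope), times = d[3]) * rep(t - t_pre, each = npix)
  out <- stack$data - array(line, d)
  fractional_stack(out, stack$sampling_rate, onset, stack$meta)
}

#' Run the full blank-subtraction pipeline on one trial
#'
#' Composition of the three canonical stages: frames-0 division of the trial
#' and of every blank, blank averaging (in fractional units, so baseline
#' heterogeneity across trials does not bias the reference), frame-by-frame
#' subtraction, and linear detrending. When the processed trial is itself a
#' blank and `leave_one_out = TRUE`, it is excluded from the blank average.
#'
#' @param trial a [trial_stack()].
#' @param blanks list of blank [trial_stack()]s.
#' @param end_window passed to [linear_detrend()].
#' @param leave_one_out exclude the trial itself from the blank average when
#'   it appears among `blanks` (matched on experiment and trial number).
#' @param mask_nonpositive passed to [frames0_divide()].
#' @return A [fractional_stack()] of dF/F values.
#' @export
run_blank_pipeline <- function(trial, blanks, end_window = NULL,
                               leave_one_out = FALSE,
                               mask_nonpositive = FALSE) {
  if (length(blanks) == 0L) stop("no blank trials supplied")
  if (leave_one_out) {
    keep <- vapply(blanks, function(b) {
      !(b$meta$experiment_number == trial$meta$experiment_number &&
          b$meta$trial_number == trial$meta$trial_number)
    }, logical(1))
    blanks <- blanks[keep]
    if (length(blanks) == 0L)
      stop("leave-one-out removed the only blank trial")
  }
  frac <- frames0_divide(trial, mask_nonpositive)
  blank_mean <- average_blanks(lapply(blanks, frames0_divide,
                                      mask_nonpositive = mask_nonpositive))
  linear_detrend(blank_subtract(frac, blank_mean), end_window)
}
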