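# Session-level aggregation and reporting: ROI timecourses, condition
# averages, trial variability, method comparison, heartbeat-contribution
# maps, and publication-oriented figures.

#' Region of interest
#'
#' @param mask H x W logical matrix with at least one `TRUE` pixel.
#' @param label short name for reports and figures.
#' @return An object of class `vsdi_roi`.
#' @export
roi <- function(mask, label = "roi") {
  if (!is.matrix(mask) || !is.logical(mask)) mask <- matrix(as.logical(mask),
                                                            nrow = nrow(mask))
  if (!any(mask)) stop("ROI mask has no pixels")
  structure(list(mask = mask, label = label), class = "vsdi_roi")
}

#' @rdname roi
#' @param H,W image dimensions.
#' @param center `c(row, col)`, 1-based.
#' @param radius radius in pixels; a pixel belongs to the disk when its
#'   center lies strictly within the radius.
#' @export
roi_disk <- function(H, W, center, radius, label = "disk") {
  d <- sqrt(outer((seq_len(H) - center[1])^2, (seq_len(W) - center[2])^2, `+`))
  roi(d < radius, label)
}

#' Read/write an ROI as a NIfTI label image
#'
#' ROIs are stored as H x W x 1 integer label volumes (nonzero = inside).
#'
#' @param r a `vsdi_roi`.
#' @param path output path.
#' @return `path` (write) / a `vsdi_roi` (read).
#' @export
write_roi <- function(r, path) {
  stopifnot(inherits(r, "vsdi_roi"))
  vol <- t(r$mask) * 1L
  dim(vol) <- c(dim(vol), 1L)
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) == 3L) vol <- vol[, , 1]
  roi(t(vol) != 0, label = sub("\\.nii(\\.gz)?$", "", basename(path)))
}

as_dff_array <- function(x) {
  if (inherits(x, "vsdi_fit")) return(x$dff)
  if (inherits(x, c("fractional_stack", "trial_stack"))) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a 3D array, fractional_stack, trial_stack or vsdi_fit")
}

#' ROI-averaged timecourse
#'
#' Unweighted mean over the ROI pixels for each frame. `NaN` pixels (masked
#' upstream) are excluded, with the exclusion count reported via a message.
#'
#' @param stack H x W x T array, `fractional_stack`, `trial_stack` or
#'   `vsdi_fit` (its dF/F is used).
#' @param r a `vsdi_roi` with matching spatial dimensions.
#' @return Numeric vector of length T.
#' @export
roi_timecourse <- function(stack, r) {
  stopifnot(inherits(r, "vsdi_roi"))
  arr <- as_dff_array(stack)
  d <- dim(arr)
  if (!identical(d[1:2], dim(r$mask)))
    stop("ROI dimensions do not match the stack")
  m <- matrix(arr, d[1] * d[2], d[3])[as.vector(r$mask), , drop = FALSE]
  n_bad <- sum(!is.finite(m[, 1]))
  if (n_bad > 0)
    message(n_bad, " masked pixel(s) excluded from ROI average")
  colMeans(m, na.rm = TRUE)
}

#' Condition-averaged ROI timecourse
#'
#' Per-frame mean and sample standard deviation of the ROI timecourses over
#' all trials of one condition.
#'
#' @param stacks list of denoised trial movies (see [roi_timecourse()] for
#'   accepted types).
#' @param codes integer vector of condition codes, one per stack.
#' @param condition the condition to average.
#' @param r a `vsdi_roi`.
#' @return List with `mean` and `sd` (length-T vectors) and `n`; with a
#'   single trial `sd` is reported as 0 and flagged by `single_trial`.
#' @export
condition_average <- function(stacks, codes, condition, r) {
  if (length(stacks) != length(codes))
    stop("one condition code per stack required")
  idx <- which(codes == condition)
  if (length(idx) == 0L) stop("no trials with condition ", condition)
  tcs <- vapply(stacks[idx], roi_timecourse, r = r,
                numeric(dim(as_dff_array(stacks[[idx[1]]]))[3]))
  tcs <- matrix(tcs, ncol = length(idx))
  m <- rowMeans(tcs)
  s <- if (length(idx) > 1L) apply(tcs, 1L, stats::sd) else rep(0, length(m))
  list(mean = m, sd = s, n = length(idx), single_trial = length(idx) == 1L)
}

#' Trial-by-trial ROI timecourses and their dispersion
#'
#' All per-trial ROI timecourses without reduction, plus the per-frame
#' across-trial standard deviation; optionally a spaghetti figure.
#'
#' @inheritParams condition_average
#' @param plot_file optional PNG path for a spaghetti plot.
#' @return List with `timecourses` (T x n matrix), `dispersion` (length-T
#'   per-frame sd) and `time_s`.
#' @export
trial_variability <- function(stacks, r, plot_file = NULL) {
  if (length(stacks) == 0L) stop("empty session")
  tcs <- vapply(stacks, roi_timecourse, r = r,
                numeric(dim(as_dff_array(stacks[[1]]))[3]))
  tcs <- matrix(tcs, ncol = length(stacks))
  disp <- if (ncol(tcs) > 1L) apply(tcs, 1L, stats::sd) else rep(0, nrow(tcs))
  out <- list(timecourses = tcs, dispersion = disp,
              time_s = seq_len(nrow(tcs)) - 1)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 800, height = 500)
    graphics::matplot(tcs, type = "l", lty = 1,
                      col = grDevices::grey(0.6, 0.5),
                      xlab = "frame", ylab = "dF/F",
                      main = paste0("Trial variability (", r$label, ")"))
    graphics::lines(rowMeans(tcs), lwd = 2)
    grDevices::dev.off()
  }
  out
}

#' Compare two denoising methods on the same trials
#'
#' Pairs the trialwise ROI timecourses produced by two methods on the same
#' trial set and summarizes their difference.
#'
#' @param denoised_a,denoised_b lists of denoised movies for the same trials
#'   in the same order.
#' @param r a `vsdi_roi`.
#' @return List with `mean_a`, `mean_b` (trial-mean timecourses),
#'   `difference` (per-frame) and `rms_difference`.
#' @export
compare_methods <- function(denoised_a, denoised_b, r) {
  if (length(denoised_a) != length(denoised_b) || length(denoised_a) == 0L)
    stop("method outputs must cover the same non-empty trial set")
  ta <- vapply(denoised_a, roi_timecourse, r = r,
               numeric(dim(as_dff_array(denoised_a[[1]]))[3]))
  tb <- vapply(denoised_b, roi_timecourse, r = r,
               numeric(dim(as_dff_array(denoised_b[[1]]))[3]))
  if (!identical(dim(ta), dim(tb))) stop("frame-count mismatch between methods")
  ma <- rowMeans(matrix(ta, ncol = length(denoised_a)))
  mb <- rowMeans(matrix(tb, ncol = length(denoised_b)))
  diff <- ma - mb
  list(mean_a = ma, mean_b = mb, difference = diff,
       rms_difference = sqrt(mean(diff^2)))
}

#' Spatial map of the heartbeat contribution
#'
#' Per pixel, the fractional heartbeat amplitude estimated by the linear
#' model: `sqrt(b_sin^2 + b_cos^2) / b0`, summed over the heartbeat
#' harmonics present in the design. Fractional units (normalized by the
#' baseline coefficient).
#'
#' For a single trial the map is computed from that trial's coefficients.
#' Passing a list of fits (same design) yields the session-level map: the
#' sine/cosine coefficients are averaged across trials before taking the
#' modulus, which suppresses both coefficient noise and the positive
#' (Rayleigh) bias the modulus would otherwise inherit from it. Because
#' acquisition is heartbeat-triggered, trial phases are near-aligned and
#' coefficient averaging loses almost no true amplitude.
#'
#' @param fit a `vsdi_fit`, or a list of them sharing one design, whose
#'   design contains heartbeat sine/cosine pairs (the first oscillation
#'   frequency).
#' @return H x W numeric map.
#' @export
heartbeat_contribution_map <- function(fit) {
  fits <- if (inherits(fit, "vsdi_fit")) list(fit) else fit
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "vsdi_fit")))
    stop("expected a vsdi_fit or a list of them")
  design <- fits[[1]]$design
  freqs <- design$info$frequencies
  if (length(freqs) == 0L)
    stop("design contains no heartbeat regressors")
  f1 <- freqs[1]
  beta <- Reduce(`+`, lapply(fits, `[[`, "beta")) / length(fits)
  b0 <- beta[, , design$partition$constant]
  total <- 0
  found <- FALSE
  for (h in seq_len(design$info$n_harmonics)) {
    si <- match(sprintf("sin_f%.6g_h%d", f1, h), design$labels)
    ci <- match(sprintf("cos_f%.6g_h%d", f1, h), design$labels)
    if (is.na(si) || is.na(ci)) next
    found <- TRUE
    total <- total + sqrt(beta[, , si]^2 + beta[, , ci]^2)
  }
  if (!found) stop("design contains no heartbeat regressors")
  total / b0
}

#' Timecourse table and figure for a condition series
#'
#' Writes a TSV (frame, time_s, mean, sd, n) per condition and a summary
#' figure with sd bands, the shape the session report is built from.
#'
#' @inheritParams condition_average
#' @param conditions conditions to include (default: all nonzero codes).
#' @param sampling_rate Hz, for the time axis.
#' @param out_dir output directory.
#' @param prefix filename prefix.
#' @return Data frame of all written rows, invisibly.
#' @export
write_condition_report <- function(stacks, codes, r, sampling_rate,
                                   out_dir, prefix = "conditions",
                                   conditions = NULL) {
  if (is.null(conditions)) conditions <- sort(unique(codes[codes != 0]))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cc in conditions) {
    ca <- condition_average(stacks, codes, cc, r)
    tab <- data.frame(condition = cc, frame = seq_along(ca$mean) - 1L,
                      time_s = (seq_along(ca$mean) - 1) / sampling_rate,
                      mean = ca$mean, sd = ca$sd, n = ca$n)
    utils::write.table(tab,
                       file.path(out_dir, sprintf("%s_cond%02d.tsv", prefix, cc)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[as.character(cc)]] <- tab
  }
  all_rows <- do.call(rbind, rows)
  fig <- file.path(out_dir, paste0(prefix, ".png"))
  grDevices::png(fig, width = 900, height = 550)
  cols <- grDevices::hcl.colors(max(length(conditions), 2L), "viridis")
  ylim <- range(all_rows$mean + all_rows$sd, all_rows$mean - all_rows$sd)
  graphics::plot(NULL, xlim = range(all_rows$time_s), ylim = ylim,
                 xlab = "time (s)", ylab = "dF/F",
                 main = paste0("Condition-averaged dF/F (", r$label, ")"))
  for (i in seq_along(conditions)) {
    tab <- rows[[as.character(conditions[i])]]
    graphics::polygon(c(tab$time_s, rev(tab$time_s)),
                      c(tab$mean + tab$sd, rev(tab$mean - tab$sd)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(tab$time_s, tab$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = paste("cond", conditions),
                   col = cols[seq_along(conditions)], lwd = 2, bty = "n")
  grDevices::dev.off()
  invisible(all_rows)
}
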