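# Per-pixel ordinary least squares on the trial design matrix, dF/F
# denoising, and residual-whiteness diagnostics.

#' Fit the linear model at every pixel of a trial
#'
#' Solves `y = X beta + eps` independently for each pixel's raw-intensity
#' timecourse by ordinary least squares, through one QR factorization of the
#' design shared across all pixels (no explicit inverse). Fitting operates
#' on raw intensities: the constant-regressor coefficient is itself the
#' baseline estimate, so no frames-0 division precedes the fit. Refuses
#' rank-deficient designs.
#'
#' @param stack a [trial_stack()] (or `fractional_stack`).
#' @param design a `vsdi_design` from [build_design_matrix()] with the same
#'   number of frames.
#' @param centered compute the denoised dF/F with the constant contribution
#'   removed (default `TRUE`; see [denoise()]).
#' @param mask_nonpositive passed to [denoise()].
#' @return An object of class `vsdi_fit`: `beta` (H x W x P), `residuals`
#'   and `dff` (H x W x T), `r_squared` and `dw` (H x W), plus the `design`.
#' @export
fit_glm <- function(stack, design, centered = TRUE, mask_nonpositive = FALSE) {
  stopifnot(inherits(design, "vsdi_design"))
  X <- design$X
  d <- dim(stack$data)
  if (d[3] != nrow(X))
    stop("stack has ", d[3], " frames but design has ", nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  Y <- matrix(aperm(stack$data, c(3L, 1L, 2L)), nrow = d[3])  # T x (H*W)
  beta <- qr.coef(qrX, Y)                                     # P x (H*W)
  fitted <- X %*% beta
  res <- Y - fitted
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  rss <- colSums(res^2)
  r2 <- ifelse(tss > 0, pmax(0, pmin(1, 1 - rss / tss)), NA_real_)
  dw <- durbin_watson_cols(res)
  fit <- structure(list(
    beta = array(t(beta), c(d[1], d[2], ncol(X)),
                 dimnames = list(NULL, NULL, design$labels)),
    residuals = array(t(res), c(d[1], d[2], d[3])),
    dff = NULL,
    r_squared = matrix(r2, d[1], d[2]),
    dw = matrix(dw, d[1], d[2]),
    design = design,
    sampling_rate = stack$sampling_rate,
    onset_frame = stack$onset_frame,
    meta = stack$meta), class = "vsdi_fit")
  fit$dff <- denoise(fit, stack, design, centered = centered,
                     mask_nonpositive = mask_nonpositive)
  fit
}

#' @export
print.vsdi_fit <- function(x, ...) {
  d <- dim(x$residuals)
  cat(sprintf(
    "<vsdi_fit> %dx%d pixels, %d frames, %d regressors; median R2 %.3f, median DW %.2f\n",
    d[1], d[2], d[3], dim(x$beta)[3], stats::median(x$r_squared, na.rm = TRUE),
    stats::median(x$dw, na.rm = TRUE)))
  invisible(x)
}

#' Extract denoised dF/F from a fitted trial
#'
#' Removes the fitted noise components and normalizes by the baseline
#' coefficient. In as-printed mode, `dFF = (y - Xn bn) / b0`; in centered
#' mode (default) the constant contribution is also removed,
#' `dFF = (y - X0 b0 - Xn bn) / b0`, so blank-like pixels fluctuate
#' around 0.
#'
#' @param fit a `vsdi_fit`.
#' @param stack the trial that was fitted.
#' @param design the design used for the fit (defaults to `fit$design`).
#' @param centered remove the constant contribution (default `TRUE`).
#' @param mask_nonpositive pixels with baseline coefficient <= 0 become
#'   `NaN` (with a warning reporting the count) instead of raising an error.
#' @return H x W x T array of dF/F values.
#' @export
denoise <- function(fit, stack, design = fit$design, centered = TRUE,
                    mask_nonpositive = FALSE) {
  stopifnot(inherits(fit, "vsdi_fit"), inherits(design, "vsdi_design"))
  d <- dim(stack$data)
  X <- design$X
  beta <- matrix(aperm(fit$beta, c(3L, 1L, 2L)), nrow = ncol(X))  # P x npix
  Y <- matrix(aperm(stack$data, c(3L, 1L, 2L)), nrow = d[3])
  b0 <- beta[design$partition$constant, ]
  bad <- b0 <= 0
  if (any(bad)) {
    if (!mask_nonpositive)
      stop(sum(bad), " pixel(s) have non-positive baseline coefficient")
    warning(sum(bad), " pixel(s) with non-positive baseline masked as NaN")
    b0[bad] <- NA_real_
  }
  rm_idx <- design$partition$noise
  if (centered) rm_idx <- c(design$partition$constant, rm_idx)
  noise_fit <- if (length(rm_idx))
    X[, rm_idx, drop = FALSE] %*% beta[rm_idx, , drop = FALSE]
  else 0
  dff <- sweep(Y - noise_fit, 2L, b0, `/`)
  dff[is.na(dff)] <- NaN
  aperm(array(dff, c(d[3], d[1], d[2])), c(2L, 3L, 1L))
}

# Vectorized DW over the columns of a T x n residual matrix.
durbin_watson_cols <- function(E) {
  den <- colSums(E^2)
  num <- colSums((E[-1L, , drop = FALSE] - E[-nrow(E), , drop = FALSE])^2)
  ifelse(den > 0, num / den, NaN)
}

#' Durbin-Watson statistic of a residual timecourse
#'
#' `DW = sum_t (e_t - e_{t-1})^2 / sum_t e_t^2`, in `[0, 4]`; approximately
#' 2 for white residuals, below 2 under positive serial correlation
#' (`DW ~= 2 (1 - rho)` for an AR(1) process). Used as an a-posteriori
#' indicator that the fitted model captured all structured components.
#'
#' @param residual numeric vector, length >= 2, not all zero (all-zero
#'   input returns `NaN`).
#' @return The statistic.
#' @export
durbin_watson <- function(residual) {
  if (length(residual) < 2L) stop("need at least 2 residuals")
  durbin_watson_cols(matrix(residual, ncol = 1L))[1]
}

#' Residual-whiteness summary of a fitted trial
#'
#' Flags each pixel as "white" when its Durbin-Watson statistic lies inside
#' the given bounds and reports the fraction of white pixels over unmasked
#' pixels.
#'
#' @param fit a `vsdi_fit`.
#' @param bounds `(low, high)` DW acceptance interval (default
#'   `c(1.5, 2.5)`).
#' @return List with `white` (H x W logical map) and `fraction`.
#' @export
whiteness_report <- function(fit, bounds = c(1.5, 2.5)) {
  stopifnot(inherits(fit, "vsdi_fit"))
  ok <- is.finite(fit$dw)
  white <- fit$dw >= bounds[1] & fit$dw <= bounds[2] & ok
  list(white = white, fraction = sum(white) / sum(ok))
}

#' Persist a fitted trial as NIfTI volumes and a JSON sidecar
#'
#' Writes beta maps (H x W x 1 x P), dF/F and residual movies
#' (H x W x 1 x T), and the R-squared and Durbin-Watson maps (H x W), plus a
#' JSON sidecar referencing the design-matrix provenance file.
#'
#' @param fit a `vsdi_fit`.
#' @param dir output directory.
#' @param prefix filename prefix (e.g. the trial id).
#' @param design_ref path (string) recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_fit_result <- function(fit, dir, prefix, design_ref = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, name) {
    d <- dim(arr)
    if (length(d) == 2L) dim(arr) <- c(d, 1L)
    d <- dim(arr)
    vol <- aperm(arr, c(2L, 1L, 3L))
    if (length(d) == 3L && d[3] > 1L) {
      dim(vol) <- c(d[2], d[1], 1L, d[3])
    }
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, paste0(prefix, "_", name, ".nii.gz")),
                       datatype = "float")
  }
  wr(fit$beta, "beta")
  wr(fit$dff, "dff")
  wr(fit$residuals, "residuals")
  wr(fit$r_squared, "rsquared")
  wr(fit$dw, "dw")
  sidecar <- file.path(dir, paste0(prefix, "_fit.json"))
  jsonlite::write_json(
    list(prefix = prefix, design_ref = design_ref,
         labels = fit$design$labels, partition = fit$design$partition,
         sampling_rate = fit$sampling_rate, onset_frame = fit$onset_frame),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}
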