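# Axis convention (used everywhere in this package):
#   in memory  : data[row, column, frame], i.e. H x W x T
#   on disk    : 4D NIfTI-1 with dim (X = W, Y = H, Z = 1, T), float32,
#                pixdim[4] = 1/sampling_rate seconds, toffset = onset time (s)
# Frames are 0-based in all public metadata: onset_frame is the index of the
# first post-stimulus frame, so the pre-stimulus window is frames [0, onset).

#' Trial metadata
#'
#' Metadata identifying one acquired trial within a session: acquisition
#' date, experiment number within that day, trial number, and the integer
#' condition code of the stimulus. Condition code 0 is reserved for blank
#' trials (no stimulus presented).
#'
#' @param session_date acquisition date (`Date` or "YYYY-MM-DD" string).
#' @param experiment_number positive integer.
#' @param trial_number positive integer.
#' @param condition_code non-negative integer; 0 means blank trial.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(session_date, experiment_number, trial_number,
                       condition_code) {
  session_date <- as.Date(session_date)
  if (is.na(session_date)) stop("session_date is not a valid date")
  if (!is_count(experiment_number) || experiment_number < 1)
    stop("experiment_number must be a positive integer")
  if (!is_count(trial_number) || trial_number < 1)
    stop("trial_number must be a positive integer")
  if (!is_count(condition_code) || condition_code < 0)
    stop("condition_code must be a non-negative integer")
  structure(
    list(session_date = session_date,
         experiment_number = as.integer(experiment_number),
         trial_number = as.integer(trial_number),
         condition_code = as.integer(condition_code)),
    class = "trial_meta")
}

#' @rdname trial_meta
#' @param meta a `trial_meta` object.
#' @export
is_blank <- function(meta) {
  stopifnot(inherits(meta, "trial_meta"))
  meta$condition_code == 0L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

#' One trial's 2D+t fluorescence movie
#'
#' Container for a single trial: an H x W x T array of fluorescence
#' intensities (arbitrary units, indexed row, column, frame), the sampling
#' rate, the 0-based stimulus onset frame, and the trial metadata. At least
#' one pre-stimulus frame is required (`onset_frame >= 1`), since every
#' downstream normalization estimates the baseline from the pre-stimulus
#' window.
#'
#' @param data numeric H x W x T array, all values finite.
#' @param sampling_rate acquisition frequency in Hz (> 0).
#' @param onset_frame 0-based index of the first post-stimulus frame;
#'   must satisfy `1 <= onset_frame < T`.
#' @param meta a [trial_meta()] object.
#' @return An object of class `trial_stack`.
#' @export
trial_stack <- function(data, sampling_rate, onset_frame, meta) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (row, column, frame)")
  d <- dim(data)
  if (d[3] < 2L) stop("a trial needs at least 2 frames")
  if (!all(is.finite(data))) stop("trial data contains non-finite values")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (!is_count(onset_frame) || onset_frame < 1 || onset_frame >= d[3])
    stop("onset_frame must satisfy 1 <= onset_frame < T (0-based)")
  stopifnot(inherits(meta, "trial_meta"))
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         onset_frame = as.integer(onset_frame), meta = meta),
    class = "trial_stack")
}

#' @export
print.trial_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_stack> %dx%dx%d @ %g Hz, onset frame %d, %s cond %d (%s)\n",
              d[1], d[2], d[3], x$sampling_rate, x$onset_frame,
              format(x$meta$session_date, "%Y%m%d"), x$meta$condition_code,
              if (is_blank(x$meta)) "blank" else "stimulated"))
  invisible(x)
}

#' @export
dim.trial_stack <- function(x) dim(x$data)

#' Build a trial filename from metadata
#'
#' Filenames are the single source of trial identity in a session directory:
#' `<YYYYMMDD>_exp<EE>_trial<TTTT>_cond<CC>.nii[.gz]`. They are deterministic
#' and lexicographically sortable within a session. [parse_trial_filename()]
#' is the exact inverse.
#'
#' @param meta a [trial_meta()] object.
#' @param gz compress with gzip (default `TRUE`).
#' @return Filename string (no directory component).
#' @export
make_trial_filename <- function(meta, gz = TRUE) {
  stopifnot(inherits(meta, "trial_meta"))
  if (meta$experiment_number > 99L) stop("experiment_number exceeds 2 digits")
  if (meta$trial_number > 9999L) stop("trial_number exceeds 4 digits")
  if (meta$condition_code > 99L) stop("condition_code exceeds 2 digits")
  sprintf("%s_exp%02d_trial%04d_cond%02d.nii%s",
          format(meta$session_date, "%Y%m%d"),
          meta$experiment_number, meta$trial_number, meta$condition_code,
          if (gz) ".gz" else "")
}

#' @rdname make_trial_filename
#' @param filename a filename (directory components are ignored).
#' @export
parse_trial_filename <- function(filename) {
  base <- basename(filename)
  pat <- "^(\\d{8})_exp(\\d{2})_trial(\\d{4})_cond(\\d{2})\\.nii(\\.gz)?$"
  m <- regmatches(base, regexec(pat, base))[[1]]
  if (length(m) == 0L)
    stop("filename does not follow the trial naming convention: ", base)
  trial_meta(session_date = as.Date(m[2], format = "%Y%m%d"),
             experiment_number = as.integer(m[3]),
             trial_number = as.integer(m[4]),
             condition_code = as.integer(m[5]))
}

#' Write a trial stack as a 4D NIfTI-1 file
#'
#' Stores the H x W x T movie as a 4D NIfTI-1 volume with dimensions
#' (X = W, Y = H, Z = 1, T), 32-bit float voxels, `pixdim[4] = 1/sampling_rate`
#' seconds and `toffset` set to the stimulus onset time in seconds (so the
#' onset frame survives the round trip). Metadata is encoded in the filename
#' via [make_trial_filename()].
#'
#' @param stack a [trial_stack()].
#' @param path either a directory (the conventional filename is appended) or
#'   a full file path whose basename follows the naming convention.
#' @return The path written, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "trial_stack"))
  if (!all(is.finite(stack$data))) stop("refusing to write non-finite data")
  if (dir.exists(path)) {
    path <- file.path(path, make_trial_filename(stack$meta))
  } else {
    parse_trial_filename(path)  # validate basename up front
  }
  d <- dim(stack$data)
  vol <- aperm(stack$data, c(2L, 1L, 3L))       # (W, H, T)
  dim(vol) <- c(d[2], d[1], 1L, d[3])           # (W, H, 1, T)
  img <- RNifti::asNifti(vol, reference = list(
    pixdim = c(-1, 1, 1, 1, 1 / stack$sampling_rate, 0, 0, 0),
    toffset = stack$onset_frame / stack$sampling_rate))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a trial stack from a 4D NIfTI-1 file
#'
#' Counterpart of [write_stack()]: recovers the movie, sampling rate
#' (`1/pixdim[4]`), onset frame (`toffset * sampling_rate`, rounded) and the
#' trial metadata parsed from the filename.
#'
#' @param path path to a 4D NIfTI file named under the trial convention.
#' @param onset_frame optional override when the file's `toffset` field was
#'   not written by this package.
#' @return A [trial_stack()].
#' @export
read_stack <- function(path, onset_frame = NULL) {
  meta <- parse_trial_filename(path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D NIfTI file, got ", length(d), " dimensions")
  if (d[3] != 1L)
    stop("expected a singleton third (Z) axis, got length ", d[3])
  hdr <- RNifti::niftiHeader(img)
  dt <- hdr$pixdim[5]
  if (!is.finite(dt) || dt <= 0) stop("invalid time step in NIfTI header")
  fs <- 1 / dt
  if (is.null(onset_frame)) {
    onset_frame <- as.integer(round(hdr$toffset * fs))
    if (onset_frame < 1L)
      stop("onset frame not recoverable from header toffset; ",
           "pass onset_frame explicitly")
  }
  vol <- as.array(img)
  dim(vol) <- c(d[1], d[2], d[4])               # (W, H, T)
  data <- aperm(vol, c(2L, 1L, 3L))             # (H, W, T)
  trial_stack(data, sampling_rate = fs, onset_frame = onset_frame, meta = meta)
}

#' Index a session directory and write the condition table
#'
#' Scans trial files, checks that the session is homogeneous (identical
#' H, W, T, sampling rate and onset frame across trials — required for blank
#' averaging and for sharing one design matrix), and writes a tab-separated
#' "condition file" with one row per trial, sorted by
#' (experiment_number, trial_number).
#'
#' @param paths a session directory or a character vector of trial file paths.
#' @param table_path where to write the TSV condition table; default
#'   `conditions.tsv` inside the session directory (or alongside the first
#'   file). `NA` skips writing.
#' @return A `session_index`: a data frame with columns `trial_id`,
#'   `filename`, `condition`, `onset_frame`, `n_frames`, `sampling_rate_hz`
#'   plus hidden attributes `H`, `W` and `paths`.
#' @export
build_condition_table <- function(paths, table_path = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    dir <- paths
    paths <- list.files(
      dir, pattern = "^\\d{8}_exp\\d{2}_trial\\d{4}_cond\\d{2}\\.nii(\\.gz)?$",
      full.names = TRUE)
    if (is.null(table_path)) table_path <- file.path(dir, "conditions.tsv")
  } else if (is.null(table_path)) {
    table_path <- file.path(dirname(paths[1]), "conditions.tsv")
  }
  if (length(paths) == 0L) stop("no trial files found")
  recs <- lapply(paths, function(p) {
    meta <- parse_trial_filename(p)
    hdr <- RNifti::niftiHeader(p)
    d <- hdr$dim
    if (d[1] != 4L) stop("not a 4D NIfTI file: ", p)
    fs <- 1 / hdr$pixdim[5]
    data.frame(
      trial_id = sprintf("exp%02d_trial%04d",
                         meta$experiment_number, meta$trial_number),
      filename = basename(p),
      condition = meta$condition_code,
      onset_frame = as.integer(round(hdr$toffset * fs)),
      n_frames = d[5],
      sampling_rate_hz = fs,
      experiment_number = meta$experiment_number,
      trial_number = meta$trial_number,
      H = d[3], W = d[2],
      path = p,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  dup <- duplicated(tab[, c("experiment_number", "trial_number")])
  if (any(dup))
    stop("duplicate (experiment, trial) pairs: ",
         paste(tab$trial_id[dup], collapse = ", "))
  for (col in c("H", "W", "n_frames", "sampling_rate_hz", "onset_frame")) {
    if (length(unique(tab[[col]])) != 1L)
      stop("heterogeneous ", col, " across trials: ",
           paste(unique(tab[[col]]), collapse = ", "), " (offenders: ",
           paste(tab$trial_id[tab[[col]] != tab[[col]][1]], collapse = ", "),
           ")")
  }
  tab <- tab[order(tab$experiment_number, tab$trial_number), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.na(table_path)) {
    utils::write.table(
      tab[, c("trial_id", "filename", "condition", "onset_frame",
              "n_frames", "sampling_rate_hz")],
      table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(tab, class = c("session_index", "data.frame"))
}

#' @export
print.session_index <- function(x, ...) {
  cat(sprintf("<session_index> %d trials (%d blank), %dx%dx%d @ %g Hz\n",
              nrow(x), sum(x$condition == 0), x$H[1], x$W[1],
              x$n_frames[1], x$sampling_rate_hz[1]))
  invisible(x)
}

#' Spatial/temporal block-mean binning
#'
#' Reduces data volume by averaging non-overlapping s x s pixel blocks and
#' runs of k frames. Trailing rows/columns/frames that do not fill a complete
#' block are dropped, so every output value is an exact block mean. The
#' sampling rate is divided by the temporal factor and the onset frame mapped
#' to `floor(onset/k)`.
#'
#' @param stack a [trial_stack()].
#' @param spatial_factor integer s >= 1 applied to both rows and columns.
#' @param temporal_factor integer k >= 1.
#' @return A binned [trial_stack()].
#' @export
bin_stack <- function(stack, spatial_factor = 1L, temporal_factor = 1L) {
  stopifnot(inherits(stack, "trial_stack"))
  s <- as.integer(spatial_factor); k <- as.integer(temporal_factor)
  if (s < 1L || k < 1L) stop("binning factors must be >= 1")
  d <- dim(stack$data)
  if (s > d[1] || s > d[2]) stop("spatial factor exceeds image size")
  if (k > d[3]) stop("temporal factor exceeds frame count")
  H2 <- d[1] %/% s; W2 <- d[2] %/% s; T2 <- d[3] %/% k
  x <- stack$data[seq_len(H2 * s), seq_len(W2 * s), seq_len(T2 * k),
                  drop = FALSE]
  # fold each axis into (factor, reduced) and average over the factor axes
  dim(x) <- c(s, H2, s, W2, k, T2)
  out <- apply(x, c(2L, 4L, 6L), mean)
  onset2 <- max(1L, stack$onset_frame %/% k)  # keep >=1 pre-stim frame
  trial_stack(out, sampling_rate = stack$sampling_rate / k,
              onset_frame = onset2, meta = stack$meta)
}
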