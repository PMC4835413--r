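#' Construct an MEG recording object
#'
#' A recording is a channels-by-samples signal block in femtotesla with its
#' sampling rate, ordered channel ids and quality-control flags.
#'
#' @param signals Numeric matrix, channels x samples (fT).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_ids Character vector matching the rows of `signals`.
#' @param subject_id Subject identifier.
#' @param qc_flags Character subset of `c("artifact_excess", "head_movement")`.
#' @param band Optional band (see [as_band()]) when the recording has been
#'   band-filtered.
#' @return A `meg_recording` object.
#' @export
meg_recording <- function(signals, sampling_rate,
                          channel_ids = rownames(signals),
                          subject_id = "subject", qc_flags = character(),
                          band = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("signals must be a numeric matrix (channels x samples)")
  if (!all(is.finite(signals))) stop("signals must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (is.null(channel_ids))
    channel_ids <- sprintf("MEG%03d", seq_len(nrow(signals)))
  if (length(channel_ids) != nrow(signals))
    stop("channel_ids must match the number of rows of signals")
  bad <- setdiff(qc_flags, c("artifact_excess", "head_movement"))
  if (length(bad)) stop("unknown qc flag(s): ", paste(bad, collapse = ", "))
  rownames(signals) <- channel_ids
  if (!is.null(band)) band <- as_band(band)
  structure(list(subject_id = subject_id, signals = signals,
                 sampling_rate = sampling_rate, channel_ids = channel_ids,
                 qc_flags = unique(qc_flags), band = band),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat("<meg_recording> ", x$subject_id, ": ", nrow(x$signals), " ch x ",
      ncol(x$signals), " samples @ ", x$sampling_rate, " Hz",
      if (!is.null(x$band)) paste0(" [", x$band$name, " band]"), "\n",
      sep = "")
  if (length(x$qc_flags))
    cat("  qc: ", paste(x$qc_flags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Remove the direct-current offset from every channel
#'
#' @param rec A [meg_recording()].
#' @return The recording with each channel's mean subtracted.
#' @export
remove_dc <- function(rec) {
  stopifnot(inherits(rec, "meg_recording"))
  rec$signals <- rec$signals - rowMeans(rec$signals)
  rec
}

#' Flag a recording containing excessive magnetic artifacts
#'
#' Adds the `artifact_excess` QC flag when any sample exceeds the amplitude
#' threshold (default 6 pT = 6000 fT) in absolute value.  The signal data
#' are never modified; exclusion is a downstream, auditable choice.
#'
#' @param rec A [meg_recording()].
#' @param threshold_fT Amplitude threshold in fT (default 6000).
#' @return The recording, with `qc_flags` possibly extended.
#' @export
flag_artifact <- function(rec, threshold_fT = 6000) {
  stopifnot(inherits(rec, "meg_recording"))
  if (!is.numeric(threshold_fT) || threshold_fT <= 0)
    stop("threshold_fT must be positive")
  if (max(abs(rec$signals)) > threshold_fT)
    rec$qc_flags <- unique(c(rec$qc_flags, "artifact_excess"))
  rec
}

#' Head-movement rejection rule
#'
#' Compares the three fiducial coil positions (nasion, left/right
#' preauricular) measured at the start and end of a recording and reports
#' whether the maximum Euclidean coil displacement exceeds the limit
#' (default 5 mm), i.e. whether the dataset should be marked bad.
#'
#' @param start,end 3 x 3 numeric matrices, one coil per row, mm.
#' @param limit_mm Displacement limit in mm.
#' @return `TRUE` iff movement is beyond `limit_mm`.
#' @examples
#' p <- diag(3) * 10
#' flag_head_movement(p, p)            # FALSE: no movement
#' @export
flag_head_movement <- function(start, end, limit_mm = 5) {
  start <- as.matrix(start); end <- as.matrix(end)
  if (!all(dim(start) == c(3, 3)) || !all(dim(end) == c(3, 3)))
    stop("start and end must be 3 x 3 matrices (coils x xyz)")
  if (!all(is.finite(start)) || !all(is.finite(end)))
    stop("coil coordinates must be finite")
  disp <- sqrt(rowSums((end - start)^2))
  max(disp) > limit_mm
}

#' Trim filter edge transients
#'
#' Drops the first and last `trim_s` seconds of a recording before
#' connectivity estimation, provided the recording is at least
#' `min_duration_s` long; shorter recordings pass through unchanged.
#'
#' @param rec A [meg_recording()].
#' @param trim_s Seconds trimmed from each end (default 2).
#' @param min_duration_s Minimum duration for trimming to apply (default 20).
#' @return The (possibly trimmed) recording.
#' @export
trim_edges <- function(rec, trim_s = 2, min_duration_s = 20) {
  stopifnot(inherits(rec, "meg_recording"))
  n <- ncol(rec$signals)
  if (n / rec$sampling_rate < min_duration_s) return(rec)
  k <- round(trim_s * rec$sampling_rate)
  if (2 * k >= n) return(rec)
  rec$signals <- rec$signals[, (k + 1):(n - k), drop = FALSE]
  rec
}

#' Mean band power of a recording
#'
#' Average over channels of the per-channel mean squared amplitude, in
#' fT^2.  Applied to a band-filtered recording this is the subject's band
#' power entering the group ANOVA.
#'
#' @param rec A [meg_recording()].
#' @return Scalar power in fT^2.
#' @export
band_power <- function(rec) {
  stopifnot(inherits(rec, "meg_recording"))
  mean(rec$signals^2)
}
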