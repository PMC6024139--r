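#' Four-channel frontal EEG record
#'
#' Container for a single subject's frontal EEG time series as acquired by
#' a 4-electrode frontal montage (Fp1, Fp2, F7, F8) at 250 Hz. Samples are
#' stored as a channels-by-time matrix in microvolts.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz; the montage this package models records
#'   at 250 Hz.
#' @param channels character vector of channel labels, one per row of
#'   `samples`.
#' @param subject_id subject identifier.
#' @return An object of class `eeg_record` with fields `subject_id`, `fs`,
#'   `channels`, `samples` and `duration` (seconds).
#' @export
eeg_record <- function(samples, fs = 250,
                       channels = c("Fp1", "Fp2", "F7", "F8"),
                       subject_id = "s1") {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channels))
    stop("samples must have one row per channel")
  if (nrow(samples) != 4L)
    stop("exactly 4 channels expected (Fp1, Fp2, F7, F8)")
  if (fs != 250)
    stop("sampling rate must be 250 Hz")
  if (any(!is.finite(samples)))
    stop("non-finite samples")
  structure(
    list(subject_id = as.character(subject_id), fs = fs,
         channels = channels, samples = samples,
         duration = ncol(samples) / fs),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> subject %s: %d channels (%s), %.1f s @ %g Hz\n",
              x$subject_id, nrow(x$samples),
              paste(x$channels, collapse = ", "), x$duration, x$fs))
  invisible(x)
}

#' Extract a time slice of an EEG record
#'
#' Uses the package-wide half-open time convention `[start, start + duration)`
#' with time measured in seconds from record start.
#'
#' @param record an [eeg_record].
#' @param start slice start in seconds from record start.
#' @param duration slice length in seconds.
#' @return An `eeg_record` covering the requested slice.
#' @export
slice_record <- function(record, start, duration) {
  stopifnot(inherits(record, "eeg_record"))
  if (start < 0 || start + duration > record$duration + 1e-9)
    stop("slice outside record")
  i0 <- floor(start * record$fs) + 1L
  n <- round(duration * record$fs)
  eeg_record(record$samples[, i0:(i0 + n - 1L), drop = FALSE],
             fs = record$fs, channels = record$channels,
             subject_id = record$subject_id)
}
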