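# File formats: minimal EDF (16-bit, 1-s data records) for EEG, and the
# CSV dialects for anesthesia logs and subject metadata. The EDF subset
# written here covers exactly what the pipeline needs: 4 signals in
# physical units of microvolts at 250 Hz with integer-second duration.

.pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write an EEG record to an EDF file
#'
#' Minimal EDF writer: 16-bit samples, one-second data records, physical
#' dimension microvolts. Physical min/max are set per channel from the
#' data, so round-trip error is at most one quantization step. The record
#' duration must be an integer number of seconds.
#'
#' @param record an [eeg_record].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (abs(record$duration - round(record$duration)) > 1e-9)
    stop("EDF writer requires an integer number of seconds")
  nrec <- as.integer(round(record$duration))
  ns <- nrow(record$samples)
  pmin_ <- apply(record$samples, 1, min) - 1e-6
  pmax_ <- apply(record$samples, 1, max) + 1e-6
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(.pad(x, n), con, nchars = n, eos = NULL)
  wr("0", 8)
  wr(record$subject_id, 80)
  wr("anestheeg synthetic", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(nrec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (ch in record$channels) wr(ch, 16)
  for (ch in record$channels) wr("synthetic frontal EEG", 80)
  for (ch in record$channels) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%.6g", v), 8)
  for (v in pmax_) wr(sprintf("%.6g", v), 8)
  for (ch in record$channels) wr("-32768", 8)
  for (ch in record$channels) wr("32767", 8)
  for (ch in record$channels) wr("", 80)
  for (ch in record$channels) wr(fs, 8)
  for (ch in record$channels) wr("", 32)
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((record$samples[s, idx] - pmin_[s]) / scale[s]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EEG record from an EDF file
#'
#' Counterpart of [write_edf()]. Requires the four frontal channels
#' Fp1, Fp2, F7, F8 (an explicit error names any missing channel) and
#' physical units of microvolts.
#'
#' @param path EDF file path.
#' @param subject_id optional override of the subject id stored in the
#'   header.
#' @return An [eeg_record].
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)
  sid <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  want <- c("Fp1", "Fp2", "F7", "F8")
  missing_ch <- setdiff(want, labels)
  if (length(missing_ch))
    stop("EDF missing channel(s): ", paste(missing_ch, collapse = ", "))
  if (any(units[match(want, labels)] != "uV"))
    stop("EDF channels must be in uV")
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- matrix(0, ns, nrec * spr[1] * recdur)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      samples[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dmin[s]) * scale[s] + pmin_[s]
    }
  }
  samples <- samples[match(want, labels), , drop = FALSE]
  eeg_record(samples, fs = spr[1] / recdur, channels = want,
             subject_id = if (is.null(subject_id)) sid else subject_id)
}

#' Read an anesthesia-log CSV
#'
#' Dialect: UTF-8, header row, columns `time_s`, `kind`, `value`, `units`.
#' Times must be nondecreasing and values non-negative.
#'
#' @param path CSV path.
#' @return Anesthesia-log data frame.
#' @export
read_log_csv <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "kind", "value", "units")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("log CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(diff(log$time_s) < 0)) stop("log times must be nondecreasing")
  if (any(log$value < 0)) stop("negative dose or rate in log")
  kinds <- c("propofol_rate_set", "propofol_bolus", "midazolam", "fentanyl",
             "inhaled_on", "inhaled_off")
  bad <- setdiff(unique(log$kind), kinds)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  log
}

#' Write an anesthesia-log CSV
#' @param log anesthesia-log data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_log_csv <- function(log, path) {
  write.csv(log[, c("time_s", "kind", "value", "units")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a subject-metadata CSV
#'
#' Dialect: UTF-8, header row; requires columns `subject_id`, `group`
#' (ASD/NT), `age` (years), `sex` (male/female), `epilepsy` (logical).
#'
#' @param path CSV path.
#' @return Metadata data frame.
#' @export
read_meta_csv <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "epilepsy")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(meta$group %in% c("ASD", "NT"))) stop("group must be ASD or NT")
  if (any(meta$age < 2 | meta$age > 30)) stop("ages must be within [2, 30]")
  meta$epilepsy <- as.logical(meta$epilepsy)
  meta
}
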