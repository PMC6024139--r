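# Selection of the per-case 120-s analysis epoch from the anesthesia log,
# with artifact and suppression screening.

.EPOCH_S <- 120
.WASHOUT_S <- 300

#' Find candidate stable-infusion epochs
#'
#' Scans candidate epoch starts (1-s grid by default) and applies the three
#' log rules: (a) the propofol infusion rate is constant over the whole
#' 120-s epoch and over the 300 s preceding it (no rate-change event in
#' `(start - 300, start + 120)`, and a positive rate set at or before
#' `start - 300`); (b) no bolus, midazolam or fentanyl event in
#' `(start - 300, start + 120)` (a drug given exactly 5 min before the
#' epoch qualifies); (c) the epoch starts at least 300 s after the last
#' discontinuation of inhaled anesthetic, with no inhaled agent running.
#'
#' @param log anesthesia-log data frame (`time_s`, `kind`, `value`).
#' @param record the matching [eeg_record] (for the duration).
#' @param epoch_s epoch length (s), fixed at 120 by the analysis design.
#' @param washout_s washout requirement (s), default 300.
#' @param step candidate-start grid step (s), default 1.
#' @return Data frame of candidates: `start`, `duration`, `qualifying`,
#'   `rejection_reason` (one of `none`, `drug_within_5min`,
#'   `inhaled_within_5min`, `no_stable_infusion`), ordered by start.
#' @export
find_stable_epochs <- function(log, record, epoch_s = .EPOCH_S,
                               washout_s = .WASHOUT_S, step = 1) {
  if (is.null(log) || nrow(log) == 0) stop("empty anesthesia log")
  dur <- record$duration
  if (any(log$time_s > dur)) stop("log events beyond record duration")
  starts <- seq(0, dur - epoch_s, by = step)
  rate_t <- log$time_s[log$kind == "propofol_rate_set"]
  rate_v <- log$value[log$kind == "propofol_rate_set"]
  drug_t <- log$time_s[log$kind %in% c("propofol_bolus", "midazolam",
                                       "fentanyl")]
  inh_on <- log$time_s[log$kind == "inhaled_on"]
  inh_off <- log$time_s[log$kind == "inhaled_off"]
  reason <- character(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    r <- "none"
    # (c) inhaled anesthetic: fully off and >= washout since discontinuation
    last_on <- if (any(inh_on <= s)) max(inh_on[inh_on <= s]) else -Inf
    last_off <- if (any(inh_off <= s)) max(inh_off[inh_off <= s]) else -Inf
    if (is.finite(last_on) && last_on > last_off) {
      r <- "inhaled_within_5min"
    } else if (is.finite(last_off) && s - last_off < washout_s) {
      r <- "inhaled_within_5min"
    }
    # (a) stable infusion over epoch and preceding washout
    if (r == "none") {
      unstable <- any(rate_t > s - washout_s & rate_t < s + epoch_s)
      set_before <- rate_t <= s - washout_s
      has_rate <- any(set_before) &&
        rate_v[max(which(set_before))] > 0
      if (unstable || !has_rate) r <- "no_stable_infusion"
    }
    # (b) no other anesthetic drug within washout before or during epoch
    if (r == "none" &&
        any(drug_t > s - washout_s & drug_t < s + epoch_s))
      r <- "drug_within_5min"
    reason[i] <- r
  }
  data.frame(start = starts, duration = epoch_s,
             qualifying = reason == "none", rejection_reason = reason,
             stringsAsFactors = FALSE)
}

#' Screen a 120-s EEG segment for artifacts and suppression
#'
#' Passes only when no sample exceeds the amplitude ceiling, no 1-s window
#' has variance above `var_factor` times the median 1-s window variance of
#' the segment, and the suppression detector reports zero events inside the
#' segment.
#'
#' @param segment an [eeg_record] slice of the candidate epoch.
#' @param amp_ceiling_uv absolute amplitude ceiling (default 500 uV).
#' @param var_factor variance-ceiling multiple of the median per-second
#'   variance (default 10).
#' @return A list with `pass` (logical) and `reason` (`"none"`,
#'   `"artifact"` or `"suppression"`).
#' @export
artifact_check <- function(segment, amp_ceiling_uv = 500, var_factor = 10) {
  stopifnot(inherits(segment, "eeg_record"))
  if (max(abs(segment$samples)) >= amp_ceiling_uv)
    return(list(pass = FALSE, reason = "artifact"))
  fs <- segment$fs
  nsec <- floor(ncol(segment$samples) / fs)
  v <- sapply(seq_len(nsec), function(s) {
    idx <- ((s - 1) * fs + 1):(s * fs)
    mean(apply(segment$samples[, idx, drop = FALSE], 1, var))
  })
  if (any(v > var_factor * median(v)))
    return(list(pass = FALSE, reason = "artifact"))
  if (nrow(detect_suppression_events(segment)) > 0)
    return(list(pass = FALSE, reason = "suppression"))
  list(pass = TRUE, reason = "none")
}

#' Select the analysis epoch for one case
#'
#' Walks the qualifying stable-infusion candidates in start order and
#' returns the earliest one whose EEG passes [artifact_check()]. Ties among
#' qualifying epochs are broken deterministically by earliest start.
#'
#' @inheritParams find_stable_epochs
#' @param ... passed to [artifact_check()].
#' @return A one-row data frame: `subject_id`, `start`, `duration`,
#'   `qualifying`, `rejection_reason`. When no epoch qualifies, `start` is
#'   `NA` and `rejection_reason` reports why the last candidate failed
#'   (or the dominant log-rule failure when none were log-eligible).
#' @export
select_epoch <- function(record, log, epoch_s = .EPOCH_S,
                         washout_s = .WASHOUT_S, step = 1, ...) {
  cand <- find_stable_epochs(log, record, epoch_s, washout_s, step)
  ok <- cand[cand$qualifying, , drop = FALSE]
  if (nrow(ok) == 0) {
    tab <- table(cand$rejection_reason)
    return(data.frame(subject_id = record$subject_id, start = NA_real_,
                      duration = epoch_s, qualifying = FALSE,
                      rejection_reason = names(which.max(tab)),
                      stringsAsFactors = FALSE))
  }
  last_reason <- "artifact"
  for (i in seq_len(nrow(ok))) {
    chk <- artifact_check(slice_record(record, ok$start[i], epoch_s), ...)
    if (chk$pass)
      return(data.frame(subject_id = record$subject_id, start = ok$start[i],
                        duration = epoch_s, qualifying = TRUE,
                        rejection_reason = "none", stringsAsFactors = FALSE))
    last_reason <- chk$reason
  }
  data.frame(subject_id = record$subject_id, start = NA_real_,
             duration = epoch_s, qualifying = FALSE,
             rejection_reason = last_reason, stringsAsFactors = FALSE)
}
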