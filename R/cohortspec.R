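# Age-varying population spectrogram: per-frequency median spectra over
# sliding age windows.

#' Age-varying cohort spectrogram
#'
#' At each grid age `a` (from `lo_age` to `hi_age` in steps of `step`), the
#' output spectrum is the per-frequency median over all subjects whose age
#' satisfies `|age - a| <= halfwidth`. One epoch spectrum per subject is
#' expected. Ages with no subjects in the window are flagged missing (NA)
#' rather than interpolated. The median is taken in the dB domain; since
#' the median commutes with monotone transforms this matches the
#' linear-domain median exactly.
#'
#' @param spectra list of per-subject `spectral_estimate` objects on a
#'   common frequency grid.
#' @param ages numeric vector of subject ages (years), one per spectrum.
#' @param lo_age,hi_age age grid limits (default 2 and 23 years).
#' @param halfwidth sliding-window half-width (default 2 years).
#' @param step age grid spacing (default 0.5 years).
#' @return An object of class `age_varying_spectrogram`: `age_grid`,
#'   `freqs`, `power_db` (age x frequency matrix, NA where missing) and
#'   `n_subjects_per_bin`.
#' @export
age_varying_spectrogram <- function(spectra, ages, lo_age = 2, hi_age = 23,
                                    halfwidth = 2.0, step = 0.5) {
  if (length(spectra) == 0) stop("no subjects")
  if (length(spectra) != length(ages))
    stop("one age per spectrum required")
  f0 <- spectra[[1]]$freqs
  for (s in spectra)
    if (length(s$freqs) != length(f0) || any(abs(s$freqs - f0) > 1e-9))
      stop("frequency grid mismatch across subjects")
  db <- do.call(rbind, lapply(spectra, `[[`, "power_db"))  # subject x freq
  age_grid <- seq(lo_age, hi_age, by = step)
  pow <- matrix(NA_real_, length(age_grid), length(f0))
  n_bin <- integer(length(age_grid))
  for (i in seq_along(age_grid)) {
    sel <- abs(ages - age_grid[i]) <= halfwidth
    n_bin[i] <- sum(sel)
    if (n_bin[i] > 0)
      pow[i, ] <- apply(db[sel, , drop = FALSE], 2, median)
  }
  structure(list(age_grid = age_grid, freqs = f0, power_db = pow,
                 n_subjects_per_bin = n_bin),
            class = "age_varying_spectrogram")
}

#' @export
print.age_varying_spectrogram <- function(x, ...) {
  cat(sprintf(paste0("<age_varying_spectrogram> %d age bins (%.1f-%.1f y),",
                     " %d freqs; %d empty bins\n"),
              length(x$age_grid), min(x$age_grid), max(x$age_grid),
              length(x$freqs), sum(x$n_subjects_per_bin == 0)))
  invisible(x)
}

#' Band power profile of an age-varying spectrogram
#'
#' Extracts mean-density band power (dB) at each grid age.
#'
#' @param avs an `age_varying_spectrogram`.
#' @param band a band name from [eeg_bands()] or numeric `c(lo, hi)`.
#' @return Numeric vector of band powers (dB) along the age grid (NA where
#'   the bin is empty).
#' @export
age_band_profile <- function(avs, band) {
  stopifnot(inherits(avs, "age_varying_spectrogram"))
  lim <- .band_limits(band)
  sel <- avs$freqs >= lim[1] & avs$freqs < lim[2]
  if (!any(sel)) stop("no frequency bins inside band")
  apply(avs$power_db[, sel, drop = FALSE], 1, function(db)
    if (all(is.na(db))) NA_real_ else 10 * log10(mean(10^(db / 10))))
}
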