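#' Canonical EEG frequency bands
#'
#' The frequency bands used throughout the analysis: slow (0.1-1 Hz),
#' alpha (8-13 Hz), slow-delta (0.1-4 Hz) and total (0.1-40 Hz).
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("slow", "alpha", "slow_delta", "total"),
             lo = c(0.1, 8, 0.1, 0.1),
             hi = c(1, 13, 4, 40),
             stringsAsFactors = FALSE)
}

.band_limits <- function(band) {
  if (is.character(band)) {
    b <- eeg_bands()
    i <- match(band, b$name)
    if (is.na(i)) stop("unknown band: ", band)
    c(b$lo[i], b$hi[i])
  } else {
    band <- as.numeric(band)
    if (length(band) != 2 || band[1] >= band[2]) stop("band must be c(lo, hi) with lo < hi")
    band
  }
}

# linear spectral density floor (uV^2/Hz) applied before conversion to dB
.SPEC_FLOOR <- 1e-12

.db <- function(p) 10 * log10(pmax(p, .SPEC_FLOOR))

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the `k` most spectrally concentrated DPSS tapers for a window of
#' `n_samples` points at time-halfbandwidth product `nw`, using the Slepian
#' tridiagonal commuting-matrix formulation solved by Sturm-sequence
#' bisection and inverse iteration (compiled), so long windows remain cheap.
#' Tapers are orthonormal and ordered by decreasing spectral concentration.
#'
#' @param n_samples window length in samples.
#' @param nw time-halfbandwidth product; the taper energy is concentrated in
#'   `[-nw/n_samples, nw/n_samples]` cycles/sample.
#' @param k number of tapers; must satisfy `k <= 2 * nw - 1`.
#' @return An `n_samples` x `k` matrix, one taper per column, with the
#'   tridiagonal eigenvalues in `attr(, "eigenvalues")`.
#' @export
dpss_tapers <- function(n_samples, nw, k) {
  if (k > 2 * nw - 1)
    stop("taper count k must satisfy k <= 2*nw - 1")
  if (k < 1 || n_samples <= k)
    stop("need n_samples > k >= 1")
  key <- sprintf("dpss_%d_%g_%d", n_samples, nw, k)
  cached <- .anestheeg_cache[[key]]
  if (!is.null(cached)) return(cached)
  res <- dpss_tridiag(as.integer(n_samples), nw / n_samples, as.integer(k))
  v <- res$vectors
  # polarity convention: largest-magnitude element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  attr(v, "eigenvalues") <- res$values
  .anestheeg_cache[[key]] <- v
  v
}

.detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

#' Multitaper power spectrum of a single-channel segment
#'
#' Estimates the one-sided power spectral density by averaging squared
#' Fourier magnitudes over DPSS tapers. Each segment is detrended
#' (constant + linear) before tapering. Density is in microvolts squared
#' per Hz; dB values are `10*log10` of density with a floor of 1e-12.
#'
#' @param x numeric vector, one channel of EEG in microvolts.
#' @param fs sampling rate (Hz).
#' @param nw time-halfbandwidth product (default 6, suited to a full 120-s
#'   epoch where the slow band must be resolved).
#' @param k taper count (default 11 = 2*nw - 1).
#' @param tapers optional taper matrix overriding the DPSS default (e.g. a
#'   single rectangular taper reproduces the periodogram).
#' @param detrend remove constant + linear trend first (default TRUE).
#' @return A `spectral_estimate` with fields `freqs` (Hz), `power`
#'   (linear density), `power_db`, and `taper_params`.
#' @export
multitaper_spectrum <- function(x, fs, nw = 6, k = 11, tapers = NULL,
                                detrend = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0 || any(!is.finite(x))) stop("empty or non-finite input")
  if (n < 2 * fs) stop("segment must be at least 2 s long")
  if (is.null(tapers)) tapers <- dpss_tapers(n, nw, k) else k <- ncol(tapers)
  if (detrend) x <- .detrend(x)
  xt <- tapers * x                       # n x k
  ft <- stats::mvfft(xt)
  nf <- floor(n / 2) + 1L
  s <- Mod(ft[seq_len(nf), , drop = FALSE])^2 / fs
  s <- rowMeans(s)
  # one-sided scaling: double everything except DC (and Nyquist when n even)
  one <- rep(2, nf); one[1] <- 1
  if (n %% 2 == 0) one[nf] <- 1
  s <- s * one
  freqs <- (seq_len(nf) - 1) * fs / n
  spectral_estimate(freqs, s,
                    taper_params = list(nw = nw, k = k,
                                        window_s = n / fs, step_s = NA_real_))
}

#' Construct a spectral estimate object
#'
#' @param freqs strictly increasing frequency grid (Hz).
#' @param power linear power density (uV^2/Hz); a vector, or a time-by-
#'   frequency matrix for time-resolved estimates.
#' @param taper_params list of estimation settings (nw, k, window_s, step_s).
#' @param times optional window-center times (s) for time-resolved estimates.
#' @return An object of class `spectral_estimate`.
#' @export
spectral_estimate <- function(freqs, power, taper_params = list(),
                              times = NULL) {
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(!is.finite(power))) stop("non-finite power")
  structure(list(freqs = freqs, power = power, power_db = .db(power),
                 taper_params = taper_params, times = times),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  tm <- if (is.null(x$times)) "spectrum" else
    sprintf("spectrogram (%d windows)", length(x$times))
  cat(sprintf("<spectral_estimate> %s, %d freqs in [%.3g, %.3g] Hz\n",
              tm, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Multitaper spectrogram of an EEG record
#'
#' Sliding-window multitaper estimate, one spectrum per window, averaged
#' over channels in the linear-power domain. Window centers are reported as
#' times. Note that a `window` shorter than twice the period of the lowest
#' frequency of interest cannot resolve that band (the 0.1-1 Hz slow band
#' needs long windows); pass `warn_below_hz` to be warned.
#'
#' @param record an [eeg_record].
#' @param window window length (s), default 2.
#' @param step window step (s), default 0.1.
#' @param nw,k taper parameters (default nw = 3, k = 5).
#' @param warn_below_hz if non-NULL, warn when `window < 2 / warn_below_hz`.
#' @return A time-resolved `spectral_estimate` (`power` is windows x freqs,
#'   `times` are window centers in seconds).
#' @export
multitaper_spectrogram <- function(record, window = 2, step = 0.1,
                                   nw = 3, k = 5, warn_below_hz = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  if (window > record$duration) stop("window longer than record")
  if (!is.null(warn_below_hz) && window < 2 / warn_below_hz)
    warning(sprintf("window %.3g s cannot resolve %.3g Hz", window,
                    warn_below_hz))
  fs <- record$fs
  nwin <- floor(window * fs)
  nstep <- round(step * fs)
  starts <- seq(1L, ncol(record$samples) - nwin + 1L, by = nstep)
  tapers <- dpss_tapers(nwin, nw, k)
  nf <- floor(nwin / 2) + 1L
  pow <- matrix(0, length(starts), nf)
  for (w in seq_along(starts)) {
    acc <- numeric(nf)
    for (ch in seq_len(nrow(record$samples))) {
      seg <- record$samples[ch, starts[w]:(starts[w] + nwin - 1L)]
      sp <- multitaper_spectrum(seg, fs, tapers = tapers)
      acc <- acc + sp$power
    }
    pow[w, ] <- acc / nrow(record$samples)
  }
  freqs <- (seq_len(nf) - 1) * fs / nwin
  spectral_estimate(freqs, pow,
                    taper_params = list(nw = nw, k = k, window_s = window,
                                        step_s = step),
                    times = (starts - 1) / fs + window / 2)
}

#' Average spectral estimates across channels
#'
#' Channel spectra are averaged in the linear-power domain by default, then
#' converted back to dB (averaging in the dB domain is available as an
#' option). All inputs must share the same frequency grid.
#'
#' @param per_channel list of `spectral_estimate` objects on a common grid.
#' @param domain `"linear"` (default) or `"db"`.
#' @return A single `spectral_estimate`.
#' @export
average_channels <- function(per_channel, domain = c("linear", "db")) {
  domain <- match.arg(domain)
  stopifnot(length(per_channel) >= 1)
  f0 <- per_channel[[1]]$freqs
  for (s in per_channel)
    if (length(s$freqs) != length(f0) || any(abs(s$freqs - f0) > 1e-9))
      stop("frequency grid mismatch across channels")
  if (domain == "linear") {
    p <- Reduce(`+`, lapply(per_channel, `[[`, "power")) / length(per_channel)
  } else {
    db <- Reduce(`+`, lapply(per_channel, `[[`, "power_db")) /
      length(per_channel)
    p <- 10^(db / 10)
  }
  spectral_estimate(f0, p, taper_params = per_channel[[1]]$taper_params,
                    times = per_channel[[1]]$times)
}

#' Band power of a spectral estimate in dB
#'
#' Returns `10*log10` of the mean linear power density over the frequency
#' bins falling in `[lo, hi)` (half-open band edges). The band must be
#' resolvable: its lower edge may not fall below the frequency resolution
#' of the estimate, and its upper edge may not exceed the grid.
#'
#' @param spectrum a `spectral_estimate`.
#' @param band a band name from [eeg_bands()] or a numeric `c(lo, hi)` in Hz.
#' @return Band power in dB; a vector (one value per window) for
#'   time-resolved estimates.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  lim <- .band_limits(band)
  df <- spectrum$freqs[2] - spectrum$freqs[1]
  if (lim[1] < df - 1e-12)
    stop(sprintf("band lower edge %.3g Hz below frequency resolution %.3g Hz",
                 lim[1], df))
  if (lim[2] > max(spectrum$freqs) + df)
    stop("band upper edge beyond resolved frequencies")
  sel <- spectrum$freqs >= lim[1] & spectrum$freqs < lim[2]
  if (!any(sel)) stop("no frequency bins inside band")
  if (is.matrix(spectrum$power)) {
    .db(rowMeans(spectrum$power[, sel, drop = FALSE]))
  } else {
    .db(mean(spectrum$power[sel]))
  }
}

#' Channel-averaged multitaper spectrum of an analysis epoch
#'
#' Convenience wrapper: slices `[start, start + duration)` from the record,
#' estimates the multitaper spectrum of each channel, and averages channels
#' in the linear domain. Defaults resolve the slow band over the full 120-s
#' epoch.
#'
#' @param record an [eeg_record].
#' @param start epoch start (s).
#' @param duration epoch length (s), default 120.
#' @param nw,k taper parameters (default nw = 6, k = 11).
#' @return A `spectral_estimate`.
#' @export
epoch_spectrum <- function(record, start, duration = 120, nw = 6, k = 11) {
  sl <- slice_record(record, start, duration)
  per_ch <- lapply(seq_len(nrow(sl$samples)), function(ch)
    multitaper_spectrum(sl$samples[ch, ], sl$fs, nw = nw, k = k))
  average_channels(per_ch)
}
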