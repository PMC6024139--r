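# Shared fixtures and independent oracles used across the test files.

# one-row subject metadata for waveform synthesis
fixture_meta <- function(age = 10, group = "NT", id = "t1") {
  data.frame(subject_id = id, group = group, age = age, sex = "male",
             epilepsy = FALSE, weight = 40, infusion = 250, bolus = 1.5,
             midazolam = 0, fentanyl = 0.7, suppression = FALSE,
             stringsAsFactors = FALSE)
}

# broadband-noise record with known amplitude, for detector fixtures
fixture_noise_record <- function(duration = 120, sd_uv = 30, seed = 1,
                                 fs = 250) {
  set.seed(seed)
  eeg_record(matrix(rnorm(4 * duration * fs, 0, sd_uv), 4),
             fs = fs, subject_id = "noise")
}

# independent periodogram oracle: one-sided PSD from a bare FFT
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  nf <- floor(n / 2) + 1
  p <- Mod(fft(x)[1:nf])^2 / (n * fs)
  one <- rep(2, nf); one[1] <- 1
  if (n %% 2 == 0) one[nf] <- 1
  p * one
}

# independent burst-suppression oracle: brute-force scan of every 60-s
# window (each candidate window can be slid right until its left edge
# meets an event start, so anchoring windows at event starts is exhaustive)
oracle_grade <- function(events) {
  if (nrow(events) == 0) return(0L)
  st <- sort(events$start)
  burst <- FALSE
  for (t0 in st)
    if (sum(st >= t0 & st <= t0 + 60) >= 3) { burst <- TRUE; break }
  as.integer(burst || any(events$duration >= 10))
}

# random non-overlapping suppression event sets for property tests
random_event_set <- function(n_events, span = 600) {
  if (n_events == 0)
    return(data.frame(start = numeric(0), duration = numeric(0)))
  starts <- sort(runif(n_events, 0, span))
  durs <- runif(n_events, 0.5, 8)
  keep <- rep(TRUE, n_events)
  if (n_events > 1)
    for (i in 2:n_events)
      if (starts[i] < starts[max(which(keep[1:(i - 1)]))] +
          durs[max(which(keep[1:(i - 1)]))]) keep[i] <- FALSE
  data.frame(start = starts[keep], duration = durs[keep])
}
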