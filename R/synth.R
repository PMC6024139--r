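# Synthetic cohort generator: subject metadata, anesthesia logs and EEG
# records carrying the age- and group-dependent band-power structure the
# downstream analysis assumes.

# Cohort-level constants: group means/SDs and proportions of the baseline
# table the generator is parameterized by.
.COHORT_PARAMS <- list(
  ASD = list(age_mean = 10.88, age_sd = 5.25, male = 0.857, epilepsy = 0.095,
             infusion_mean = 239.88, infusion_sd = 32.69,
             bolus_mean = 1.34, bolus_sd = 1.13,
             midaz_prob = 0.20, midaz_dose = 0.05,
             fent_mean = 0.71, fent_sd = 0.62,
             suppression_rate = 0.230),
  NT = list(age_mean = 13.29, age_sd = 5.27, male = 0.555, epilepsy = 0,
            infusion_mean = 256.11, infusion_sd = 37.15,
            bolus_mean = 2.03, bolus_sd = 1.52,
            midaz_prob = 0.04, midaz_dose = 0.05,
            fent_mean = 0.74, fent_sd = 0.58,
            suppression_rate = 0.122))

# Anchor points (age in years, power in dB) through which the cubic
# band-power trajectories are interpolated. The values at 2.33, 5.42, 10.8
# and 22.5 years are the published posterior-mean powers; the remaining
# anchor per curve pins the early-childhood rise so each cubic peaks in
# childhood and declines monotonically afterwards.
.TRAJECTORY_ANCHORS <- list(
  alpha = list(
    NT  = cbind(age = c(2, 5.42, 7, 22.5),    db = c(15.8, 18.86, 19.3, 11.89)),
    ASD = cbind(age = c(2, 5.42, 7, 22.5),    db = c(14.9, 17.65, 18.1, 6.37))),
  slow = list(
    NT  = cbind(age = c(2.33, 7, 10.8, 22.5), db = c(14.20, 18.3, 18.99, 13.95)),
    ASD = cbind(age = c(2.33, 6, 10.8, 22.5), db = c(17.05, 17.9, 16.93, 11.56))))

# age at which trajectory cubics are centered (pooled cohort mean age)
.TRAJ_CENTER_AGE <- 12.624

.traj_coef <- function(band, group) {
  key <- sprintf("traj_%s_%s", band, group)
  co <- .anestheeg_cache[[key]]
  if (is.null(co)) {
    anch <- .TRAJECTORY_ANCHORS[[band]][[group]]
    ca <- anch[, "age"] - .TRAJ_CENTER_AGE
    co <- solve(outer(ca, 0:3, `^`), anch[, "db"])
    .anestheeg_cache[[key]] <- co
  }
  co
}

#' Age trajectory of propofol-induced band power
#'
#' Evaluates the generator's target band power (dB) at a given age, for one
#' cohort and band. Each trajectory is the cubic polynomial in centered age
#' interpolating the published posterior-mean powers at selected ages plus
#' one early-childhood anchor; every trajectory peaks in childhood and
#' declines monotonically afterwards through 23 years.
#'
#' @param age age in years, within `[2, 23]`.
#' @param group `"ASD"` or `"NT"`.
#' @param band `"slow"` or `"alpha"`.
#' @param clamp if TRUE, ages outside `[2, 23]` are clamped to the range
#'   instead of raising an error.
#' @return Target band power in dB (vectorized over `age`).
#' @export
power_trajectory <- function(age, group = c("ASD", "NT"),
                             band = c("slow", "alpha"), clamp = FALSE) {
  group <- match.arg(group); band <- match.arg(band)
  if (clamp) age <- pmin(pmax(age, 2), 23)
  if (any(age < 2 | age > 23)) stop("age outside [2, 23]")
  co <- .traj_coef(band, group)
  drop(outer(age - .TRAJ_CENTER_AGE, 0:3, `^`) %*% co)
}

#' Trajectory model description
#'
#' Returns the anchor points and centered-age cubic coefficients underlying
#' [power_trajectory()] for one band and group.
#'
#' @inheritParams power_trajectory
#' @return A list with `band`, `group`, `anchor_points` (age, dB),
#'   `center_age` and `coefficients` (intercept through cubic term in
#'   centered age).
#' @export
trajectory_model <- function(band = c("slow", "alpha"),
                             group = c("ASD", "NT")) {
  band <- match.arg(band); group <- match.arg(group)
  list(band = band, group = group,
       anchor_points = .TRAJECTORY_ANCHORS[[band]][[group]],
       center_age = .TRAJ_CENTER_AGE,
       coefficients = .traj_coef(band, group))
}

# truncated-normal sampling via inverse CDF
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Sample a synthetic cohort
#'
#' Draws subject metadata and per-subject anesthesia logs for an ASD and an
#' NT cohort, with ages, sex, epilepsy comorbidity and drug regimens drawn
#' from the group-specific distributions of the baseline cohort table, and
#' a Bernoulli burst-suppression episode indicator at group rates 0.230
#' (ASD) and 0.122 (NT).
#'
#' @param n_asd,n_nt cohort sizes (>= 1).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param duration record duration (s) encoded in each anesthesia log.
#' @return A list with `meta` (data frame: subject_id, group, age, sex,
#'   epilepsy, weight, infusion, bolus, midazolam, fentanyl, suppression)
#'   and `logs` (named list of anesthesia-log data frames).
#' @export
sample_cohort <- function(n_asd, n_nt, seed = NULL, duration = 660) {
  if (n_asd < 1 || n_nt < 1) stop("cohort sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  one_group <- function(n, group) {
    p <- .COHORT_PARAMS[[group]]
    age <- .rtnorm(n, p$age_mean, p$age_sd, 2, 23)
    data.frame(
      subject_id = sprintf("%s%04d", tolower(group), seq_len(n)),
      group = group,
      age = age,
      sex = ifelse(rbinom(n, 1, p$male) == 1, "male", "female"),
      epilepsy = rbinom(n, 1, p$epilepsy) == 1,
      weight = pmax(8, 10 + 2.8 * age + rnorm(n, 0, 4)),
      infusion = .rtnorm(n, p$infusion_mean, p$infusion_sd, 0),
      bolus = .rtnorm(n, p$bolus_mean, p$bolus_sd, 0),
      midazolam = rbinom(n, 1, p$midaz_prob) * p$midaz_dose,
      fentanyl = .rtnorm(n, p$fent_mean, p$fent_sd, 0),
      suppression = rbinom(n, 1, p$suppression_rate) == 1,
      stringsAsFactors = FALSE)
  }
  meta <- rbind(one_group(n_asd, "ASD"), one_group(n_nt, "NT"))
  rownames(meta) <- NULL
  logs <- lapply(seq_len(nrow(meta)), function(i)
    make_anesthesia_log(meta[i, ], duration = duration))
  names(logs) <- meta$subject_id
  list(meta = meta, logs = logs)
}

#' Build a single-case anesthesia log
#'
#' Encodes one case's drug events: optional midazolam premedication,
#' fentanyl at induction, one propofol bolus, an initial infusion-rate
#' setting and one rate change, leaving a stable-infusion window with a
#' full 5-minute washout of every other drug from 360 s onwards.
#'
#' @param meta one-row data frame (or list) with fields `infusion` (mcg/kg/min),
#'   `bolus` (mg/kg), `midazolam` (mg/kg) and `fentanyl` (mcg/kg).
#' @param duration record duration in seconds (>= 600).
#' @return A data frame with columns `time_s`, `kind`, `value`, `units`.
#' @export
make_anesthesia_log <- function(meta, duration = 660) {
  if (duration < 600) stop("duration must be >= 600 s")
  ev <- list()
  add <- function(t, kind, value, units)
    ev[[length(ev) + 1]] <<- data.frame(time_s = t, kind = kind,
                                        value = value, units = units,
                                        stringsAsFactors = FALSE)
  if (!is.null(meta$midazolam) && meta$midazolam > 0)
    add(2, "midazolam", meta$midazolam, "mg/kg")
  if (meta$fentanyl > 0) add(5, "fentanyl", meta$fentanyl, "mcg/kg")
  add(10, "propofol_bolus", meta$bolus, "mg/kg")
  add(15, "propofol_rate_set", 0.8 * meta$infusion, "mcg/kg/min")
  add(60, "propofol_rate_set", meta$infusion, "mcg/kg/min")
  log <- do.call(rbind, ev)
  attr(log, "duration") <- duration
  log
}

# one-sided PSD shapes (uV^2/Hz) used by the signal model ------------------

# broadband background: flat 2.5 uV^2/Hz across 1.5-35 Hz with a quadratic
# roll-on below and an exponential roll-off above; keeps the slow band well
# below its trajectory targets while holding the awake-band amplitude high
# enough that only genuine suppression approaches the detector floor.
.bg_psd <- function(f) {
  s <- rep(2.5, length(f))
  lo <- f < 1.5
  s[lo] <- 2.5 * (f[lo] / 1.5)^2
  hi <- f > 35
  s[hi] <- 2.5 * exp(-(f[hi] - 35) / 2)
  s
}

# unit-scale narrowband bumps for the slow and alpha oscillations
.slow_psd <- function(f) exp(-0.5 * ((f - 0.55) / 0.22)^2)
.alpha_psd <- function(f) exp(-0.5 * ((f - 10) / 0.85)^2)

# colored-noise synthesis by FFT shaping of white noise; psd_fun gives the
# one-sided target density for unit white-noise input
.colored_noise <- function(n, fs, psd_fun) {
  w <- rnorm(n)
  wf <- fft(w)
  freqs <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  h <- sqrt(psd_fun(abs(freqs)) * fs / 2)
  Re(fft(wf * h, inverse = TRUE)) / n
}

.band_density <- function(spec, band) {
  lim <- .band_limits(band)
  sel <- spec$freqs >= lim[1] & spec$freqs < lim[2]
  mean(spec$power[sel])
}

#' Synthesize one subject's EEG record and anesthesia log
#'
#' Builds a 4-channel frontal EEG record as broadband background noise plus
#' narrowband slow (centered 0.5 Hz) and alpha (centered 10 Hz, ~2 Hz
#' bandwidth) components. Each oscillatory component is scaled, using this
#' package's own multitaper estimate of the clean 120-s analysis epoch, so
#' that the epoch's channel-averaged band power matches the age/group
#' trajectory target to within a fraction of a dB. Channels share the
#' oscillations and differ by small independent noise. The accompanying
#' log leaves a stable-infusion epoch at 360 s with full drug washout.
#'
#' @param meta one-row data frame with `age`, `group` and drug fields (as
#'   produced by [sample_cohort()]).
#' @param duration record length in seconds (>= 600).
#' @param suppression `NULL` for none; a data frame of events
#'   (`start`, `duration` in s) to inject; or `"burst"` / `"prolonged"` for
#'   canned patterns placed before the analysis epoch.
#' @param seed optional integer seed.
#' @return A list with `record` ([eeg_record]), `log` (anesthesia-log data
#'   frame), `epoch_start` (360) and `targets` (dB targets per band).
#' @export
synthesize_eeg <- function(meta, duration = 660, suppression = NULL,
                           seed = NULL) {
  if (duration < 600) stop("duration must be >= 600 s for a valid epoch")
  if (!is.null(seed)) set.seed(seed)
  fs <- 250
  n <- round(duration * fs)
  epoch_start <- 360
  group <- as.character(meta$group)
  targets <- c(slow = power_trajectory(meta$age, group, "slow", clamp = TRUE),
               alpha = power_trajectory(meta$age, group, "alpha", clamp = TRUE))

  bg <- .colored_noise(n, fs, .bg_psd)
  base <- matrix(rnorm(4 * n, 0, 1.5), 4, n, byrow = TRUE)
  base <- sweep(base, 2, bg, `+`)
  rec0 <- eeg_record(base, fs = fs, subject_id = as.character(meta$subject_id))
  sp0 <- epoch_spectrum(rec0, epoch_start)

  shared <- 0
  for (band in c("slow", "alpha")) {
    u <- .colored_noise(n, fs, if (band == "slow") .slow_psd else .alpha_psd)
    spu <- multitaper_spectrum(u[(epoch_start * fs + 1):((epoch_start + 120) * fs)],
                               fs, nw = 6, k = 11)
    p_target <- 10^(targets[[band]] / 10)
    p0 <- .band_density(sp0, band)
    pu <- .band_density(spu, band)
    g <- (p_target - p0) / pu
    if (g < 0) {
      warning("background exceeds ", band, " band target; component omitted")
      g <- 0
    }
    shared <- shared + sqrt(g) * u
  }
  samples <- sweep(base, 2, shared, `+`)
  record <- eeg_record(samples, fs = fs,
                       subject_id = as.character(meta$subject_id))

  if (!is.null(suppression)) {
    if (is.character(suppression)) {
      suppression <- switch(match.arg(suppression, c("burst", "prolonged")),
        burst = data.frame(start = c(130, 150, 170), duration = 2),
        prolonged = data.frame(start = 140, duration = 12))
    }
    record <- inject_suppression(record, suppression)
  }
  list(record = record,
       log = make_anesthesia_log(meta, duration = duration),
       epoch_start = epoch_start, targets = targets)
}

#' Inject suppression episodes into an EEG record
#'
#' Attenuates all channels during each event so the signal envelope falls
#' below `floor_uv`; samples outside the events are untouched. Events must
#' lie within the record and must not overlap.
#'
#' @param record an [eeg_record].
#' @param events data frame with columns `start` and `duration` (seconds).
#' @param floor_uv amplitude floor in microvolts (default 2, safely below
#'   the 5 uV detector threshold).
#' @return The modified `eeg_record`.
#' @export
inject_suppression <- function(record, events, floor_uv = 2) {
  stopifnot(inherits(record, "eeg_record"))
  if (nrow(events) == 0) return(record)
  events <- events[order(events$start), , drop = FALSE]
  if (any(events$duration <= 0)) stop("event durations must be positive")
  if (any(events$start < 0) ||
      any(events$start + events$duration > record$duration + 1e-9))
    stop("events outside record duration")
  ends <- events$start + events$duration
  if (nrow(events) > 1 && any(events$start[-1] < ends[-nrow(events)]))
    stop("overlapping suppression events")
  fs <- record$fs
  s <- record$samples
  for (i in seq_len(nrow(events))) {
    idx <- (floor(events$start[i] * fs) + 1):(floor(ends[i] * fs))
    for (ch in seq_len(nrow(s))) {
      rms <- sqrt(mean(s[ch, idx]^2))
      if (rms > 0) s[ch, idx] <- s[ch, idx] * min(1, floor_uv / (4 * rms))
    }
  }
  eeg_record(s, fs = fs, channels = record$channels,
             subject_id = record$subject_id)
}

#' Random burst-suppression event pattern
#'
#' Draws an event pattern that grades positive by construction: either a
#' cluster of 3-5 short suppression events inside a 60-s span, or a single
#' prolonged event of at least 10 s. Patterns are placed before the 360-s
#' analysis epoch so the selected epoch itself stays clean.
#'
#' @param kind `"random"` (default; burst with probability 0.7),
#'   `"burst"` or `"prolonged"`.
#' @return A data frame with `start` and `duration` columns (seconds).
#' @export
make_suppression_pattern <- function(kind = c("random", "burst", "prolonged")) {
  kind <- match.arg(kind)
  if (kind == "random") kind <- if (runif(1) < 0.7) "burst" else "prolonged"
  t0 <- runif(1, 60, 260)
  if (kind == "prolonged") {
    # comfortably above the 10-s grading threshold so the grade survives
    # the detector's ~0.15-s envelope-smoothing edge bias
    data.frame(start = t0, duration = runif(1, 12, 18))
  } else {
    k <- sample(3:5, 1)
    durs <- runif(k, 1, 3)
    gaps <- runif(k - 1, 4, 12)
    starts <- t0 + cumsum(c(0, durs[-k] + gaps))
    if (starts[k] - starts[1] > 58)  # keep the cluster inside one 60-s window
      starts <- starts[1] + (starts - starts[1]) * 58 / (starts[k] - starts[1])
    data.frame(start = starts, duration = durs)
  }
}

#' Band powers drawn from the trajectory model
#'
#' Convenience generator: evaluates the band-power trajectory at each
#' subject's age and group and adds independent Gaussian noise. Used for
#' regression-scale simulations where full waveform synthesis is not
#' needed.
#'
#' @param meta cohort metadata data frame (`age`, `group`).
#' @param band `"slow"` or `"alpha"`.
#' @param noise_sd residual standard deviation in dB.
#' @param seed optional integer seed.
#' @return Numeric vector of band powers (dB), one per subject.
#' @export
trajectory_band_powers <- function(meta, band, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mapply(function(a, g) power_trajectory(a, g, band, clamp = TRUE),
         meta$age, as.character(meta$group)) +
    rnorm(nrow(meta), 0, noise_sd)
}
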