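test_that("DPSS tapers are orthonormal and match a dense eigendecomposition", {
  n <- 200; nw <- 3; k <- 5
  tp <- dpss_tapers(n, nw, k)
  expect_lt(max(abs(crossprod(tp) - diag(k))), 1e-8)
  # independent oracle: dense LAPACK eigendecomposition of the same
  # tridiagonal commuting matrix
  cw <- cos(2 * pi * nw / n)
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cw
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  Tm <- diag(d)
  for (i in 1:(n - 1)) Tm[i, i + 1] <- Tm[i + 1, i] <- e[i]
  ev <- eigen(Tm, symmetric = TRUE)
  for (j in 1:k) {
    v <- ev$vectors[, j]
    expect_lt(min(max(abs(tp[, j] - v)), max(abs(tp[, j] + v))), 1e-8)
  }
})

test_that("first taper concentrates its energy inside the design band", {
  n <- 500; nw <- 3; k <- 5
  tp <- dpss_tapers(n, nw, k)
  # concentration as a direct quadratic form with the band-limited sinc
  # kernel, evaluated independently of the taper construction
  W <- nw / n
  ij <- outer(1:n, 1:n, `-`)
  S <- ifelse(ij == 0, 2 * W, sin(2 * pi * W * ij) / (pi * ij))
  conc <- drop(t(tp[, 1]) %*% S %*% tp[, 1])
  expect_gt(conc, 0.99)
  # concentrations decrease with taper order
  concs <- vapply(1:k, function(j) drop(t(tp[, j]) %*% S %*% tp[, j]),
                  numeric(1))
  expect_true(all(diff(concs) < 0))
})

test_that("invalid taper parameter combinations are rejected", {
  expect_error(dpss_tapers(500, 3, 6), "k <= 2\\*nw - 1")
  expect_error(dpss_tapers(4, 3, 5), "n_samples > k")
})

test_that("a pure sinusoid yields a peak at its frequency with the right power", {
  fs <- 250; A <- 12
  t <- (0:4999) / fs
  sp <- multitaper_spectrum(A * sin(2 * pi * 10 * t), fs, nw = 3, k = 5)
  expect_equal(sp$freqs[which.max(sp$power)], 10)
  df <- sp$freqs[2] - sp$freqs[1]
  sel <- sp$freqs >= 8 & sp$freqs < 13
  expect_lt(abs(sum(sp$power[sel]) * df - A^2 / 2) / (A^2 / 2), 0.05)
  # alpha band dwarfs the slow band for this fixture
  expect_gte(band_power(sp, "alpha") - band_power(sp, c(0.1, 1)), 30)
})

test_that("white-noise power integrates to the variance (Parseval)", {
  fs <- 250
  set.seed(11)
  ratios <- replicate(100, {
    x <- rnorm(2500, 0, 3)
    sp <- multitaper_spectrum(x, fs, nw = 3, k = 5)
    df <- sp$freqs[2] - sp$freqs[1]
    sum(sp$power) * df / var(x)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("a single rectangular taper reduces the estimator to the periodogram", {
  fs <- 250
  set.seed(2)
  x <- rnorm(1000)
  rect <- matrix(1 / sqrt(length(x)), length(x), 1)
  sp <- multitaper_spectrum(x, fs, tapers = rect, detrend = FALSE)
  expect_equal(sp$power, oracle_periodogram(x, fs), tolerance = 1e-12)
})

test_that("degenerate and offset inputs follow the declared contracts", {
  fs <- 250
  expect_error(multitaper_spectrum(numeric(0), fs), "empty")
  expect_error(multitaper_spectrum(c(rnorm(999), NA), fs), "non-finite")
  expect_error(multitaper_spectrum(rnorm(100), fs), "at least 2 s")
  # all-zero segment: clamped at the declared spectral floor, not an error
  spz <- multitaper_spectrum(numeric(1000), fs, nw = 3, k = 5)
  expect_true(all(spz$power_db == 10 * log10(1e-12)))
  # band power invariant to a constant offset (detrending contract)
  set.seed(3)
  x <- rnorm(2500)
  s1 <- multitaper_spectrum(x, fs, nw = 3, k = 5)
  s2 <- multitaper_spectrum(x + 57, fs, nw = 3, k = 5)
  expect_equal(band_power(s1, "alpha"), band_power(s2, "alpha"),
               tolerance = 1e-10)
})

test_that("spectrogram windows tile and track nonstationarity", {
  fs <- 250
  set.seed(4)
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  alpha <- 20 * sin(2 * pi * 10 * t) * (t >= 30)   # alpha only in 2nd half
  rec <- eeg_record(matrix(rnorm(4 * n, 0, 2), 4, n, byrow = TRUE) +
                      rep(alpha, each = 4), fs = fs)
  sg <- multitaper_spectrogram(rec, window = 2, step = 2, nw = 3, k = 5)
  expect_equal(length(sg$times), floor(60 / 2))  # non-overlapping tiling
  ap <- band_power(sg, "alpha")
  expect_gte(mean(ap[sg$times > 32]) - mean(ap[sg$times < 28]), 10)
  # stationary record: alpha band power stable across windows
  rec2 <- eeg_record(matrix(rnorm(4 * n, 0, 10), 4, n, byrow = TRUE), fs = fs)
  sg2 <- multitaper_spectrogram(rec2, window = 5, step = 5, nw = 3, k = 5)
  expect_lt(diff(range(band_power(sg2, "alpha"))), 2)
  expect_warning(
    multitaper_spectrogram(rec2, window = 2, step = 10, warn_below_hz = 0.1),
    "cannot resolve")
})

test_that("channel averaging is the linear-domain mean on a common grid", {
  f <- seq(0.5, 40, 0.5)
  mk <- function(db) spectral_estimate(f, rep(10^(db / 10), length(f)))
  four <- replicate(4, mk(15), simplify = FALSE)
  expect_equal(average_channels(four)$power_db, mk(15)$power_db)
  # closed form: 10 and 20 dB average to 10*log10((10+100)/2)
  avg <- average_channels(list(mk(10), mk(20)))
  expect_equal(avg$power_db[1], 10 * log10(55), tolerance = 1e-10)
  # dB-domain option gives the arithmetic dB mean instead
  avg_db <- average_channels(list(mk(10), mk(20)), domain = "db")
  expect_equal(avg_db$power_db[1], 15, tolerance = 1e-10)
  other <- spectral_estimate(seq(1, 40, 0.5), rep(1, 79))
  expect_error(average_channels(list(mk(10), other)), "grid mismatch")
})

test_that("band power follows the mean-density definition and its preconditions", {
  f <- seq(0.1, 40, 0.1)
  flat <- spectral_estimate(f, rep(3.7, length(f)))
  for (b in eeg_bands()$name)
    expect_equal(band_power(flat, b), 10 * log10(3.7), tolerance = 1e-12)
  # slow band unresolvable on a 0.5-Hz grid
  coarse <- spectral_estimate(seq(0.5, 40, 0.5), rep(3.7, 80))
  expect_error(band_power(coarse, "slow"), "below frequency resolution")
  expect_error(band_power(flat, c(30, 80)), "beyond resolved")
})
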