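test_that("cohort sampling is deterministic and matches the target distributions", {
  c1 <- sample_cohort(1, 1, seed = 7)
  c2 <- sample_cohort(1, 1, seed = 7)
  expect_identical(c1, c2)
  expect_error(sample_cohort(0, 5), ">= 1")

  big <- sample_cohort(10000, 10000, seed = 123)
  asd <- big$meta[big$meta$group == "ASD", ]
  nt <- big$meta[big$meta$group == "NT", ]
  expect_lt(abs(mean(asd$sex == "male") - 0.857), 0.02)
  expect_lt(abs(mean(nt$sex == "male") - 0.555), 0.02)
  expect_lt(abs(mean(asd$infusion) - 239.88), 1)
  expect_lt(abs(mean(nt$infusion) - 256.11), 1)
  expect_true(all(nt$epilepsy == FALSE))
  expect_lt(abs(mean(asd$epilepsy) - 0.095), 0.02)
  expect_true(all(big$meta$age >= 2 & big$meta$age <= 23))
  expect_true(all(big$meta$weight > 0))
  # suppression episode rates
  expect_lt(abs(mean(asd$suppression) - 0.230), 0.02)
  expect_lt(abs(mean(nt$suppression) - 0.122), 0.02)
})

test_that("anesthesia logs satisfy their invariants and washout layout", {
  co <- sample_cohort(3, 3, seed = 1)
  for (log in co$logs) {
    expect_true(all(diff(log$time_s) >= 0))
    expect_true(all(log$value >= 0))
    # stable infusion with full washout from 360 s on
    other <- log$time_s[log$kind != "propofol_rate_set"]
    expect_true(all(other <= 60))
    rates <- log$time_s[log$kind == "propofol_rate_set"]
    expect_true(max(rates) <= 60)
  }
})

test_that("power trajectories pass through the published anchor powers", {
  expect_equal(power_trajectory(5.42, "NT", "alpha"), 18.86, tolerance = 0.01)
  expect_equal(power_trajectory(22.5, "NT", "alpha"), 11.89, tolerance = 0.01)
  expect_equal(power_trajectory(5.42, "ASD", "alpha"), 17.65, tolerance = 0.01)
  expect_equal(power_trajectory(22.5, "ASD", "alpha"), 6.37, tolerance = 0.01)
  expect_equal(power_trajectory(2.33, "ASD", "slow"), 17.05, tolerance = 0.01)
  expect_equal(power_trajectory(10.8, "ASD", "slow"), 16.93, tolerance = 0.01)
  expect_equal(power_trajectory(22.5, "ASD", "slow"), 11.56, tolerance = 0.01)
  expect_equal(power_trajectory(2.33, "NT", "slow"), 14.20, tolerance = 0.01)
  expect_equal(power_trajectory(10.8, "NT", "slow"), 18.99, tolerance = 0.01)
  expect_equal(power_trajectory(22.5, "NT", "slow"), 13.95, tolerance = 0.01)
  expect_error(power_trajectory(1.5, "NT", "alpha"), "age outside")
  expect_error(power_trajectory(25, "NT", "alpha"), "age outside")
  expect_equal(power_trajectory(25, "NT", "alpha", clamp = TRUE),
               power_trajectory(23, "NT", "alpha"))
})

test_that("each trajectory declines monotonically after its childhood peak", {
  ages <- seq(2, 23, 0.05)
  for (band in c("slow", "alpha")) for (group in c("ASD", "NT")) {
    v <- power_trajectory(ages, group, band)
    pk <- which.max(v)
    expect_lt(ages[pk], 11)          # peak in childhood
    expect_true(all(diff(v[pk:length(v)]) <= 1e-9))
    # anchor reproduction within 0.01 dB
    m <- trajectory_model(band, group)
    expect_equal(power_trajectory(m$anchor_points[, "age"], group, band),
                 unname(m$anchor_points[, "db"]), tolerance = 0.01)
  }
})

test_that("synthesized EEG reproduces its band-power targets (round trip)", {
  set.seed(99)
  draws <- data.frame(age = runif(10, 2.5, 22.5),
                      group = sample(c("ASD", "NT"), 10, replace = TRUE))
  for (i in seq_len(nrow(draws))) {
    syn <- synthesize_eeg(fixture_meta(draws$age[i], draws$group[i]),
                          seed = 1000 + i)
    sp <- epoch_spectrum(syn$record, syn$epoch_start)
    expect_lt(abs(band_power(sp, "slow") - syn$targets[["slow"]]), 1)
    expect_lt(abs(band_power(sp, "alpha") - syn$targets[["alpha"]]), 1)
  }
})

test_that("EEG synthesis is deterministic and validates its inputs", {
  m <- fixture_meta(8, "ASD")
  s1 <- synthesize_eeg(m, seed = 5)
  s2 <- synthesize_eeg(m, seed = 5)
  expect_identical(s1$record$samples, s2$record$samples)
  expect_error(synthesize_eeg(m, duration = 500), ">= 600")
})

test_that("suppression injection alters only the requested intervals", {
  m <- fixture_meta(6, "NT")
  syn <- synthesize_eeg(m, seed = 21)
  ev0 <- data.frame(start = numeric(0), duration = numeric(0))
  expect_identical(inject_suppression(syn$record, ev0)$samples,
                   syn$record$samples)
  expect_error(
    inject_suppression(syn$record,
                       data.frame(start = c(10, 11), duration = c(5, 5))),
    "overlapping")
  expect_error(
    inject_suppression(syn$record, data.frame(start = 655, duration = 10)),
    "outside record")
  ev <- data.frame(start = 100, duration = 12)
  rec <- inject_suppression(syn$record, ev)
  fs <- rec$fs
  inside <- (100 * fs + 100):(112 * fs - 100)
  outside <- 1:(100 * fs - 10)
  expect_lt(max(abs(rec$samples[, inside])), 5)
  expect_identical(rec$samples[, outside], syn$record$samples[, outside])
})

test_that("injected patterns are recovered by the detector and grader", {
  m <- fixture_meta(9, "NT")
  # no injection: no events
  syn <- synthesize_eeg(m, seed = 31)
  expect_equal(nrow(detect_suppression_events(syn$record)), 0)
  # three 2-s silences in 50 s: burst suppression
  ev <- data.frame(start = c(100, 125, 150), duration = 2)
  syn2 <- synthesize_eeg(m, suppression = ev, seed = 31)
  det <- detect_suppression_events(syn2$record)
  expect_equal(nrow(det), 3)
  # edge bias is slightly larger on full synthetic EEG than on the plain
  # noise fixture (higher pre-event envelope); 0.2 s is still well inside
  # the grammar's tolerances
  expect_true(all(abs(det$start - ev$start) <= 0.2))
  g <- grade_case(det, 660)
  expect_equal(g$grade, 1L)
  expect_equal(g$basis, "burst_suppression")
  # a single 12-s silence: prolonged suppression
  syn3 <- synthesize_eeg(m, suppression = "prolonged", seed = 31)
  det3 <- detect_suppression_events(syn3$record)
  expect_equal(nrow(det3), 1)
  expect_gte(det3$duration, 10)
  expect_equal(grade_case(det3, 660)$basis, "prolonged_suppression")
})

test_that("generated group separation matches the alpha contrast at 22.5 years", {
  measured <- sapply(seq_len(50), function(i) {
    g <- if (i <= 25) "ASD" else "NT"
    syn <- synthesize_eeg(fixture_meta(22.5, g), seed = 3000 + i)
    band_power(epoch_spectrum(syn$record, syn$epoch_start), "alpha")
  })
  gap <- mean(measured[26:50]) - mean(measured[1:25])
  expect_lt(abs(gap - 5.52), 1)
})
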