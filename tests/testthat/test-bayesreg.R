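sim_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", 1:n),
    group = sample(c("ASD", "NT"), n, replace = TRUE),
    age = runif(n, 2, 23),
    sex = sample(c("male", "female"), n, replace = TRUE),
    epilepsy = rbinom(n, 1, 0.1) == 1,
    infusion = rnorm(n, 250, 35),
    bolus = abs(rnorm(n, 1.8, 1.2)),
    midazolam = rbinom(n, 1, 0.15) * 0.05,
    fentanyl = abs(rnorm(n, 0.7, 0.6)),
    stringsAsFactors = FALSE)
}

test_that("the design matrix centers age and codes interactions correctly", {
  meta <- sim_meta(80)
  y <- rnorm(80)
  d <- build_design(meta, y)
  expect_lt(abs(sum(d$X[, "age"])), 1e-9)
  g <- as.integer(meta$group == "ASD")
  ca <- meta$age - mean(meta$age)
  expect_equal(unname(d$X[, "group_x_age"]), g * ca)
  expect_equal(unname(d$X[, "group_x_age3"]), g * ca^3)
  expect_equal(ncol(d$X), 14)
  # degenerate designs are rejected
  same_age <- meta; same_age$age <- 10
  expect_error(build_design(same_age, y), "rank deficient")
  expect_error(build_design(meta[, -3], y), "missing covariates: age")
  y2 <- y; y2[3] <- NA
  expect_error(build_design(meta, y2), "missing values")
})

test_that("the Gibbs sampler recovers noise-free coefficients", {
  meta <- sim_meta(60, seed = 3)
  d0 <- build_design(meta, rnorm(60))
  beta0 <- seq(-1, 1, length.out = ncol(d0$X))
  y <- drop(d0$X %*% beta0) + rnorm(60, 0, 1e-6)
  d <- build_design(meta, y)
  fit <- gibbs_sample(d, iterations = 2000, burn_in = 200, seed = 1)
  med <- fit$coefficients$median[seq_len(ncol(d$X))]
  expect_lt(max(abs(med - beta0)), 1e-3)
})

test_that("Gibbs posterior means match the closed-form conjugate posterior", {
  for (s in 1:3) {
    meta <- sim_meta(100, seed = s)
    y <- trajectory_band_powers(meta, "slow", noise_sd = 3, seed = s + 10)
    d <- build_design(meta, y)
    fit <- gibbs_sample(d, iterations = 4000, burn_in = 400, seed = s)
    betahat <- drop(solve(crossprod(d$X), crossprod(d$X, y)))
    mc_mean <- colMeans(fit$draws)
    mc_se <- apply(fit$draws, 2, sd) / sqrt(nrow(fit$draws))
    expect_true(all(abs(mc_mean - betahat) < 3 * mc_se + 1e-12))
  }
})

test_that("the residual variance posterior is consistent", {
  meta <- sim_meta(500, seed = 9)
  d0 <- build_design(meta, rnorm(500))
  y <- drop(d0$X %*% rep(0.5, ncol(d0$X))) + rnorm(500)
  fit <- gibbs_sample(build_design(meta, y), iterations = 3000,
                      burn_in = 300, seed = 2)
  s2 <- fit$coefficients$median[fit$coefficients$term == "sigma2"]
  expect_lt(abs(s2 - 1), 0.1)
  # determinism under seed
  fit2 <- gibbs_sample(build_design(meta, y), iterations = 500,
                       burn_in = 100, seed = 4)
  fit3 <- gibbs_sample(build_design(meta, y), iterations = 500,
                       burn_in = 100, seed = 4)
  expect_identical(fit2$draws, fit3$draws)
})

test_that("HPD intervals are the shortest mass-covering intervals", {
  set.seed(5)
  z <- rnorm(1e5)
  h <- hpd_interval(z, 0.80)
  expect_equal(h[1], -1.2816, tolerance = 0.05)
  expect_equal(h[2], 1.2816, tolerance = 0.05)
  expect_equal(hpd_interval(rep(3.5, 200), 0.8), c(3.5, 3.5))
  # exponential: the shortest interval is left-anchored near 0
  e <- rexp(1e5)
  he <- hpd_interval(e, 0.80)
  expect_lt(he[1], 0.01)
  expect_equal(he[2], stats::qexp(0.8), tolerance = 0.05)
  # nesting/monotonicity and containment in the sample range
  h9 <- hpd_interval(z, 0.90)
  expect_lt(h9[1], h[1]); expect_gt(h9[2], h[2])
  expect_gte(h[1], min(z)); expect_lte(h[2], max(z))
  expect_error(hpd_interval(z, 1.2), "mass")
  expect_error(hpd_interval(rnorm(10), 0.8), "100 draws")
  # equal-tailed option
  et <- hpd_interval(z, 0.80, type = "equal_tail")
  expect_equal(et, unname(quantile(z, c(0.1, 0.9))))
})

test_that("group contrasts behave under symmetry and the calibrated trajectories", {
  meta <- sim_meta(152, seed = 21)
  # null generating model: under no group effect the single-dataset
  # certainty is itself posterior-data-dependent, so average replicates
  certs <- sapply(1:20, function(r) {
    m <- sim_meta(152, seed = 300 + r)
    set.seed(400 + r)
    y <- 10 - 0.1 * (m$age - mean(m$age)) + rnorm(152, 0, 2)
    f <- gibbs_sample(build_design(m, y), iterations = 1500, burn_in = 200,
                      seed = r)
    group_contrast_at_age(f, 12)$certainty
  })
  expect_lt(abs(mean(certs) - 0.5), 0.15)

  # alpha-calibrated cohort: the ASD deficit certainty grows with age
  y_alpha <- trajectory_band_powers(meta, "alpha", noise_sd = 4, seed = 22)
  fita <- gibbs_sample(build_design(meta, y_alpha), iterations = 4000,
                       burn_in = 400, seed = 5)
  expect_gt(group_contrast_at_age(fita, 22.5)$certainty,
            group_contrast_at_age(fita, 5.42)$certainty)

  # slow power: ASD higher at 2.33 y, lower at 10.8 y, so the certainty
  # crosses 0.5 at some intermediate age
  y_slow <- trajectory_band_powers(meta, "slow", noise_sd = 4, seed = 23)
  fits <- gibbs_sample(build_design(meta, y_slow), iterations = 4000,
                       burn_in = 400, seed = 6)
  cert <- sapply(seq(2.33, 10.8, 0.25), function(a)
    group_contrast_at_age(fits, a)$certainty)
  expect_lt(cert[1], 0.5)
  expect_gt(cert[length(cert)], 0.5)
  expect_warning(group_contrast_at_age(fits, 30), "extrapolation")
})

test_that("BIC Bayes factors select the generating polynomial order", {
  meta <- sim_meta(152, seed = 31)
  ca <- meta$age - mean(meta$age)
  set.seed(32)
  picks3 <- replicate(10, {
    y <- 15 - 0.05 * ca - 0.01 * ca^3 + rnorm(152, 0, 2)
    bayes_factor_poly_order(meta, y)$selected
  })
  expect_gte(sum(picks3 == 3), 9)
  picks1 <- replicate(10, {
    y <- 15 + 0.5 * ca + rnorm(152, 0, 2)
    bayes_factor_poly_order(meta, y)$selected
  })
  expect_gte(sum(picks1 == 1), 9)
  # a model against itself has Bayes factor 1
  y <- 15 + 0.5 * ca + rnorm(152, 0, 2)
  tab <- bayes_factor_poly_order(meta, y)$table
  expect_equal(tab$bf_vs_selected[tab$order == tab$order[which.min(tab$bic)]],
               1)
})
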