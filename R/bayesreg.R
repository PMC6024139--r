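# Bayesian linear regression of band power on cubic centered age, group,
# group-by-age interactions, and anesthetic covariates, via Gibbs sampling
# under the noninformative prior p(beta, sigma^2) proportional to 1/sigma^2.

#' Build the regression design for a band-power model
#'
#' The response is per-subject band power (dB). Age is centered at the
#' cohort mean before polynomial and interaction expansion, so the group
#' main effect is the group contrast at mean age. Indicators are coded
#' 0/1 (group: ASD = 1; sex: male = 1; epilepsy: yes = 1). Covariates are
#' fit on their raw clinical scales (infusion in mcg/kg/min, boluses in
#' mg/kg, fentanyl in mcg/kg).
#'
#' @param meta cohort metadata data frame with columns `group`, `age`,
#'   `sex`, `infusion`, `bolus`, `midazolam`, `fentanyl`, `epilepsy`.
#' @param response numeric vector of band powers (dB), one per subject.
#' @param age_order polynomial order of centered age (default 3).
#' @param interactions include group-by-age-power interactions
#'   (default TRUE).
#' @param drop_constant drop covariate columns with zero variance (e.g. a
#'   cohort where nobody received midazolam) instead of raising the
#'   rank-deficiency error (default FALSE).
#' @return An object of class `regression_design`: `X`, `y`, `terms`,
#'   `center_age`.
#' @export
build_design <- function(meta, response, age_order = 3,
                         interactions = TRUE, drop_constant = FALSE) {
  if (length(response) != nrow(meta)) stop("one response per subject")
  need <- c("group", "age", "sex", "infusion", "bolus", "midazolam",
            "fentanyl", "epilepsy")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  if (any(!is.finite(response)) ||
      any(!stats::complete.cases(meta[, need])))
    stop("missing values in response or covariates")
  center_age <- mean(meta$age)
  ca <- meta$age - center_age
  g <- as.integer(meta$group == "ASD")
  X <- cbind(intercept = 1, group = g)
  for (o in seq_len(age_order)) {
    X <- cbind(X, ca^o)
    colnames(X)[ncol(X)] <- paste0("age", if (o > 1) o else "")
  }
  X <- cbind(X,
             sex = as.integer(meta$sex == "male"),
             infusion = meta$infusion,
             bolus = meta$bolus,
             midazolam = meta$midazolam,
             fentanyl = meta$fentanyl,
             epilepsy = as.integer(as.logical(meta$epilepsy)))
  if (interactions)
    for (o in seq_len(age_order)) {
      X <- cbind(X, g * ca^o)
      colnames(X)[ncol(X)] <- paste0("group_x_age",
                                     if (o > 1) o else "")
    }
  if (drop_constant) {
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v)
      length(unique(v)) > 1))
    X <- X[, keep, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, y = response, terms = colnames(X),
                 center_age = center_age, age_order = age_order),
            class = "regression_design")
}

#' Gibbs sampler for the normal linear model
#'
#' Samples from the posterior of the normal linear regression model under
#' the Jeffreys noninformative prior p(beta, sigma^2) ~ 1/sigma^2, using
#' the conjugate conditional updates beta | sigma^2 ~ N(betahat,
#' sigma^2 (X'X)^-1) and sigma^2 | beta ~ Inv-Gamma(n/2, RSS(beta)/2).
#' Defaults follow the analysis protocol: 10,000 kept iterations after
#' 1000 burn-in, thin 1.
#'
#' @param design a `regression_design`.
#' @param iterations kept iterations after burn-in (default 10000).
#' @param burn_in burn-in iterations (default 1000).
#' @param thin thinning interval (default 1).
#' @param seed optional integer seed.
#' @param hpd_mass posterior mass of the reported HPD intervals
#'   (default 0.80).
#' @return An object of class `posterior_summary`: `coefficients` (data
#'   frame with posterior `median`, `hpd_lower`, `hpd_upper` per term and
#'   for `sigma2`), `draws` (kept draws, one column per coefficient),
#'   `sigma2_draws`, `settings`, and the `design`.
#' @export
gibbs_sample <- function(design, iterations = 10000, burn_in = 1000,
                         thin = 1, seed = NULL, hpd_mass = 0.80) {
  stopifnot(inherits(design, "regression_design"))
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more subjects than coefficients")
  if (!is.null(seed)) set.seed(seed)
  XtX <- crossprod(X)
  R <- chol(XtX)                       # X'X = R'R
  betahat <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  resid0 <- y - X %*% betahat
  sig2 <- sum(resid0^2) / (n - p)
  total <- burn_in + iterations * thin
  keep <- matrix(NA_real_, iterations, p)
  keep_s2 <- numeric(iterations)
  kept <- 0L
  for (it in seq_len(total)) {
    z <- rnorm(p)
    beta <- betahat + sqrt(sig2) * backsolve(R, z)
    rss <- sum((y - X %*% beta)^2)
    sig2 <- rss / rchisq(1, df = n)
    if (!is.finite(sig2) || sig2 <= 0) stop("sampler divergence: sigma2 draw non-finite")
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      keep[kept, ] <- beta
      keep_s2[kept] <- sig2
    }
  }
  colnames(keep) <- design$terms
  summ <- function(d) {
    h <- hpd_interval(d, hpd_mass)
    c(median = median(d), hpd_lower = h[1], hpd_upper = h[2])
  }
  co <- t(apply(keep, 2, summ))
  co <- rbind(co, sigma2 = summ(keep_s2))
  structure(list(coefficients = data.frame(term = rownames(co), co,
                                           row.names = NULL),
                 draws = keep, sigma2_draws = keep_s2,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thin = thin, seed = seed,
                                 hpd_mass = hpd_mass),
                 design = design),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %d draws, %d coefficients\n",
              nrow(x$draws), ncol(x$draws)))
  co <- x$coefficients
  co[, -1] <- round(co[, -1], 3)
  print(co)
  invisible(x)
}

#' Highest posterior density interval from draws
#'
#' The shortest contiguous interval containing the requested posterior
#' mass, computed empirically by scanning the sorted draws. An
#' equal-tailed interval is available as an option.
#'
#' @param draws numeric vector of posterior draws (>= 100 for `hpd`).
#' @param mass posterior mass in (0, 1), default 0.80.
#' @param type `"hpd"` (default) or `"equal_tail"`.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.80, type = c("hpd", "equal_tail")) {
  type <- match.arg(type)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  if (type == "equal_tail") {
    return(unname(quantile(draws, c((1 - mass) / 2, 1 - (1 - mass) / 2))))
  }
  if (length(draws) < 100) stop("need at least 100 draws for an empirical HPD")
  s <- sort(draws)
  n <- length(s)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(s[1], s[n]))
  w <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(w)
  c(s[i], s[i + m])
}

#' Posterior group contrast at a given age
#'
#' Per-draw predicted difference in band power (ASD minus NT) at the given
#' age, combining the group main effect and the group-by-age interaction
#' terms evaluated at centered age. The reported certainty is the
#' posterior probability that the ASD power is below the NT power.
#'
#' @param summary a `posterior_summary` from [gibbs_sample()].
#' @param age age in years; flagged (warning) when outside the ages the
#'   model was fit on.
#' @return A list with `age`, `draws` (difference draws), `median`, and
#'   `certainty` = Pr(ASD < NT).
#' @export
group_contrast_at_age <- function(summary, age) {
  stopifnot(inherits(summary, "posterior_summary"))
  des <- summary$design
  if (age < des$center_age + min(des$X[, "age"]) ||
      age > des$center_age + max(des$X[, "age"]))
    warning("age outside the fitted range; contrast is an extrapolation")
  ca <- age - des$center_age
  d <- summary$draws[, "group"]
  for (o in seq_len(des$age_order)) {
    term <- paste0("group_x_age", if (o > 1) o else "")
    if (term %in% colnames(summary$draws))
      d <- d + summary$draws[, term] * ca^o
  }
  list(age = age, draws = d, median = median(d), certainty = mean(d < 0))
}

#' Polynomial-order selection for the age trend by Bayes factor
#'
#' Fits the model with centered-age polynomial order 1, 2 and 3 (with
#' matching group-by-age interactions) and compares orders by the BIC
#' approximation to the Bayes factor (exact Bayes factors are undefined
#' under the improper prior). The order with the largest approximate
#' marginal likelihood is selected.
#'
#' @param meta cohort metadata (as for [build_design()]).
#' @param response band powers (dB).
#' @param orders candidate orders (default 1:3).
#' @return A list with `selected` (order) and `table` (data frame: order,
#'   bic, log-marginal-likelihood approximation, Bayes factor against the
#'   best order).
#' @export
bayes_factor_poly_order <- function(meta, response, orders = 1:3) {
  stats_ <- lapply(orders, function(o) {
    d <- build_design(meta, response, age_order = o)
    n <- nrow(d$X); p <- ncol(d$X)
    rss <- sum(stats::lm.fit(d$X, d$y)$residuals^2)
    bic <- n * log(rss / n) + p * log(n)
    c(order = o, bic = bic)
  })
  tab <- as.data.frame(do.call(rbind, stats_))
  tab$logml <- -tab$bic / 2
  best <- which.min(tab$bic)
  tab$bf_vs_selected <- exp(tab$logml - tab$logml[best])
  list(selected = tab$order[best], table = tab)
}
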