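# Standardized mean differences and baseline cohort tables.

.smd_result <- function(variable, smd, detail) {
  structure(c(list(variable = variable, smd = smd, notable = smd > 0.2),
              detail),
            class = "smd_result")
}

#' Standardized mean difference for a continuous variable
#'
#' `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`: the absolute mean difference over
#' the unweighted root-mean-square of the two group SDs. Values above 0.2
#' are flagged notable (about 15% non-overlap of the two distributions).
#'
#' @param m1,s1 mean and SD of group 1.
#' @param m2,s2 mean and SD of group 2.
#' @return An `smd_result` list: `variable`, `smd`, `notable`, plus the
#'   group summaries.
#' @export
smd_continuous <- function(m1, s1, m2, s2) {
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  if (s1 == 0 && s2 == 0) stop("both SDs are zero")
  .smd_result("continuous", abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2),
              list(m1 = m1, s1 = s1, m2 = m2, s2 = s2))
}

#' Standardized mean difference for a binary variable
#'
#' With group proportions `p_i = k_i / n_i`, computes
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)` — the continuous SMD
#' applied to the Bernoulli means and variances with the same unweighted
#' pooling.
#'
#' @param k1,n1 count and denominator of group 1.
#' @param k2,n2 count and denominator of group 2.
#' @return An `smd_result` list.
#' @export
smd_binary <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n with n >= 1")
  p1 <- k1 / n1; p2 <- k2 / n2
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v == 0) stop("zero pooled variance (both proportions degenerate)")
  .smd_result("binary", abs(p1 - p2) / sqrt(v),
              list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2))
}

#' @export
print.smd_result <- function(x, ...) {
  cat(sprintf("<smd_result> %s: SMD = %.3f%s\n", x$variable, x$smd,
              if (x$notable) " (notable)" else ""))
  invisible(x)
}

#' Baseline characteristics table with SMDs
#'
#' One row per baseline variable (age, male sex, propofol infusion rate,
#' propofol bolus, midazolam, fentanyl, epilepsy comorbidity): group means
#' (SD) or counts (%), the standardized mean difference, and the notable
#' flag (SMD > 0.2).
#'
#' @param meta cohort metadata data frame (as from [sample_cohort()]),
#'   with a `group` column containing `"ASD"` and `"NT"`.
#' @return A data frame with columns `variable`, `asd`, `nt`, `smd`,
#'   `notable`; summaries are formatted to the table's display precision.
#' @export
cohort_table <- function(meta) {
  for (g in c("ASD", "NT"))
    if (sum(meta$group == g) < 1) stop("empty group: ", g)
  a <- meta[meta$group == "ASD", ]
  b <- meta[meta$group == "NT", ]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 subjects per group for SD-based SMDs")
  cont <- function(name, col) {
    # a variable nobody received has zero SD in both groups; report NA
    r <- tryCatch(smd_continuous(mean(a[[col]]), sd(a[[col]]),
                                 mean(b[[col]]), sd(b[[col]])),
                  error = function(e) NULL)
    data.frame(variable = name,
               asd = sprintf("%.2f (%.2f)", mean(a[[col]]), sd(a[[col]])),
               nt = sprintf("%.2f (%.2f)", mean(b[[col]]), sd(b[[col]])),
               smd = if (is.null(r)) NA_real_ else round(r$smd, 3),
               notable = if (is.null(r)) NA else r$notable,
               stringsAsFactors = FALSE)
  }
  bin <- function(name, x_a, x_b) {
    k1 <- sum(x_a); k2 <- sum(x_b)
    # degenerate shared proportion (e.g. no epileptics anywhere): SMD is 0/0,
    # reported as NA rather than aborting the whole table
    r <- tryCatch(smd_binary(k1, length(x_a), k2, length(x_b)),
                  error = function(e) NULL)
    data.frame(variable = name,
               asd = sprintf("%d (%.1f)", k1, 100 * k1 / length(x_a)),
               nt = sprintf("%d (%.1f)", k2, 100 * k2 / length(x_b)),
               smd = if (is.null(r)) NA_real_ else round(r$smd, 3),
               notable = if (is.null(r)) NA else r$notable,
               stringsAsFactors = FALSE)
  }
  rbind(
    cont("Age (years)", "age"),
    bin("Male sex (%)", a$sex == "male", b$sex == "male"),
    cont("Propofol infusion rate (mcg/kg/min)", "infusion"),
    cont("Propofol bolus (mg/kg)", "bolus"),
    cont("Midazolam (mg/kg)", "midazolam"),
    cont("Fentanyl (mcg/kg)", "fentanyl"),
    bin("Comorbid epilepsy (%)", a$epilepsy, b$epilepsy))
}
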