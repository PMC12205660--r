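#' Kaplan-Meier estimate with Greenwood confidence interval
#'
#' Product-limit estimator of the survival function with Greenwood-variance
#' 95\% confidence limits.  The returned step function is right-continuous
#' (the estimate drops at each event time), the convention used throughout
#' the survival literature.
#'
#' @param times Follow-up times (months), nonnegative.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param conf_type Confidence-limit transform passed to
#'   [survival::survfit()]; `"plain"` applies the Greenwood standard error
#'   directly on the survival scale.
#' @return List with `time`, `surv`, `lower`, `upper`, `n_risk`, `n_event`
#'   and the underlying `survfit` object.
#' @export
km_estimate <- function(times, events, conf_type = "plain") {
  if (any(times < 0)) stop("negative times")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = conf_type
  )
  list(time = fit$time, surv = fit$surv,
       lower = fit$lower, upper = fit$upper,
       n_risk = fit$n.risk, n_event = fit$n.event, fit = fit)
}

#' Log-rank test for two survival curves
#'
#' Standard observed-versus-expected log-rank statistic on 1 degree of
#' freedom.
#'
#' @param timesA,eventsA Follow-up times and event flags in group A.
#' @param timesB,eventsB Follow-up times and event flags in group B.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0L || length(timesB) == 0L) {
    stop("both groups must be nonempty")
  }
  time <- c(timesA, timesB)
  event <- as.integer(as.logical(c(eventsA, eventsB)))
  group <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with the Efron tie approximation.  Reports the
#' hazard ratio per unit of the covariate with Wald and likelihood-ratio
#' p-values.  Set `standardize = TRUE` to scale the covariate to unit SD
#' first, so the hazard ratio is per standard deviation.
#'
#' @param times Follow-up times.
#' @param events Event flags.
#' @param covariate Numeric covariate (e.g. a model score); must vary.
#' @param standardize Scale the covariate to unit SD before fitting.
#' @param alpha Two-sided significance level for the CI.
#' @return Object of class `cox_result`: list with `hazard_ratio`, `ci`,
#'   `log_hr`, `se`, `p_wald`, `p_likelihood_ratio`, `per_sd`.
#' @export
cox_univariate <- function(times, events, covariate, standardize = FALSE,
                           alpha = 0.05) {
  if (length(unique(covariate)) < 2L) stop("constant covariate")
  x <- if (standardize) as.numeric(scale(covariate)) else covariate
  events <- as.integer(as.logical(events))
  fit <- survival::coxph(survival::Surv(times, events) ~ x, ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - alpha / 2)
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  out <- list(
    hazard_ratio = exp(beta),
    ci = exp(c(beta - z * se, beta + z * se)),
    log_hr = beta,
    se = se,
    p_wald = 2 * stats::pnorm(-abs(beta / se)),
    p_likelihood_ratio = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    per_sd = standardize
  )
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox univariate: HR %.3f (%.3f-%.3f)%s, Wald p = %.4g, LR p = %.4g\n",
              x$hazard_ratio, x$ci[1], x$ci[2],
              if (x$per_sd) " per SD" else " per unit",
              x$p_wald, x$p_likelihood_ratio))
  invisible(x)
}

#' Stratify patients by model score
#'
#' Splits continuous scores into high/low groups either at the observed
#' median (default) or at a fixed threshold, mirroring the high-score /
#' low-score prognostic stratification.
#'
#' @param scores Continuous scores.
#' @param rule `"median_split"` or `"fixed_threshold"`.
#' @param threshold Threshold used when `rule = "fixed_threshold"`; must lie
#'   within the observed score range.
#' @return List with `group` (factor "low"/"high") and `threshold`.
#' @export
stratify_by_score <- function(scores, rule = c("median_split",
                                               "fixed_threshold"),
                              threshold = NULL) {
  rule <- match.arg(rule)
  thr <- if (rule == "median_split") {
    stats::median(scores)
  } else {
    if (is.null(threshold)) stop("fixed_threshold rule requires a threshold")
    if (threshold < min(scores) || threshold > max(scores)) {
      stop("threshold outside observed score range")
    }
    threshold
  }
  grp <- factor(ifelse(scores > thr, "high", "low"), levels = c("low", "high"))
  list(group = grp, threshold = thr)
}

#' Survival analysis of a score-stratified cohort
#'
#' Convenience wrapper: stratifies by score, then for each endpoint computes
#' KM curves per group, the log-rank test, and univariate Cox regression on
#' the continuous score.
#'
#' @param scores Model scores, one per patient.
#' @param survival_table Data frame with columns `rfs_months`, `rfs_event`,
#'   `os_months`, `os_event` aligned with `scores`.
#' @param rule,threshold Stratification rule, see [stratify_by_score()].
#' @param standardize Standardize the score in the Cox fits (HR per SD).
#' @return List with `strata` and per-endpoint `km_low`/`km_high`,
#'   `logrank`, `cox`.
#' @export
survival_by_score <- function(scores, survival_table,
                              rule = "median_split", threshold = NULL,
                              standardize = TRUE) {
  st <- stratify_by_score(scores, rule, threshold)
  hi <- st$group == "high"
  one <- function(time_col, event_col) {
    tt <- survival_table[[time_col]]
    ee <- survival_table[[event_col]]
    list(
      km_low = km_estimate(tt[!hi], ee[!hi]),
      km_high = km_estimate(tt[hi], ee[hi]),
      logrank = logrank_test(tt[!hi], ee[!hi], tt[hi], ee[hi]),
      cox = cox_univariate(tt, ee, scores, standardize = standardize)
    )
  }
  list(strata = st,
       rfs = one("rfs_months", "rfs_event"),
       os = one("os_months", "os_event"))
}
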