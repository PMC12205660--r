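#' Area under the ROC curve
#'
#' Computes the AUC by the Mann--Whitney concordance formulation: the
#' probability that a randomly chosen positive case scores higher than a
#' randomly chosen negative case, with ties counting one half.  This equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric vector of continuous scores (higher = more positive).
#' @param labels Logical or 0/1 vector of true class labels; `TRUE`/1 is the
#'   positive class (here: pathological complete response).
#' @return A single number in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc() requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise AP: sum over descending-score thresholds of
#' (recall_i - recall_{i-1}) * precision_i.  Cases with exactly equal scores
#' are grouped into a single threshold so tie handling is deterministic.
#' Precision corresponds to the positive predictive value and recall to
#' sensitivity.
#'
#' @inheritParams roc_auc
#' @return A single number in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("average_precision() requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s))          # block index per distinct score
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  last <- which(grp != c(grp[-1L], -1L)) # last element of each score block
  tp_b <- tp[last]
  n_b <- n_seen[last]
  recall <- tp_b / n_pos
  precision <- tp_b / n_b
  sum(diff(c(0, recall)) * precision)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval by inversion of binomial tails, computed through beta
#' quantiles: lower = Q_Beta(alpha/2; k, n-k+1) (0 when k = 0) and
#' upper = Q_Beta(1-alpha/2; k+1, n-k) (1 when k = n).
#'
#' @param successes Number of successes (k).
#' @param trials Number of trials (n), > 0.
#' @param alpha Two-sided significance level (default 0.05 for a 95\% CI).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(8, 8)   # lower = 0.025^(1/8) = 0.631
#' @export
clopper_pearson <- function(successes, trials, alpha = 0.05) {
  stopifnot(length(successes) == 1L, length(trials) == 1L)
  if (trials <= 0) stop("clopper_pearson() requires trials > 0")
  k <- successes
  n <- trials
  if (k < 0 || k > n) stop("successes must lie in [0, trials]")
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

# DeLong placement values: for each positive case the fraction of negatives it
# beats (ties half), and vice versa.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  # psi(x, y) = 1 if x > y, 0.5 if equal, 0 otherwise; vectorized via ranks
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance and confidence interval for a single AUC
#'
#' Placement-value variance estimator for the AUC of one score vector, with a
#' normal-approximation confidence interval truncated to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @param alpha Two-sided significance level.
#' @return List with `auc`, `var`, `ci` (length-2 vector).
#' @export
auc_ci_delong <- function(scores, labels, alpha = 0.05) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  p <- delong_placements(scores, labels)
  m <- length(p$v10)
  n <- length(p$v01)
  v <- stats::var(p$v10) / m + stats::var(p$v01) / n
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(v)
  list(auc = p$auc, var = v,
       ci = c(max(0, p$auc - half), min(1, p$auc + half)))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same cases using
#' the DeLong placement-value covariance estimator and a two-sided normal
#' reference distribution.
#'
#' @param scoresA,scoresB Paired score vectors on identical cases.
#' @inheritParams roc_auc
#' @param alpha Significance level for the CI of the AUC difference.
#' @return List with `aucA`, `aucB`, `diff`, `z`, `p`, `ci_diff`.
#' @export
delong_test <- function(scoresA, scoresB, labels, alpha = 0.05) {
  labels <- as_binary_labels(labels)
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels)) {
    stop("delong_test() requires paired scores on identical cases")
  }
  if (length(unique(labels)) < 2L) stop("both classes required")
  pa <- delong_placements(scoresA, labels)
  pb <- delong_placements(scoresB, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
    half <- 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
    half <- stats::qnorm(1 - alpha / 2) * sqrt(var_diff)
  }
  list(aucA = pa$auc, aucB = pb$auc, diff = d, z = z, p = p,
       ci_diff = c(d - half, d + half))
}

#' Bootstrap confidence interval for average precision
#'
#' Stratified (class-preserving) bootstrap percentile interval for AP.
#'
#' @inheritParams roc_auc
#' @param reps Bootstrap replicates.
#' @param alpha Two-sided significance level.
#' @param seed Integer seed for the resampling stream.
#' @return List with `ap` and `ci`.
#' @export
ap_ci_bootstrap <- function(scores, labels, reps = 2000, alpha = 0.05,
                            seed = 1L) {
  labels <- as_binary_labels(labels)
  idx_pos <- which(labels == 1L)
  idx_neg <- which(labels == 0L)
  ap <- average_precision(scores, labels)
  boot <- withr_seed(seed, {
    vapply(seq_len(reps), function(i) {
      ii <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
      average_precision(scores[ii], labels[ii])
    }, numeric(1))
  })
  list(ap = ap,
       ci = unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2))))
}

#' Confusion-matrix metrics with exact Clopper-Pearson intervals
#'
#' Standard thresholded classification metrics with pathological complete
#' response as the positive event.  Every proportion carries an exact
#' Clopper-Pearson 95\% confidence interval.
#'
#' @param pred_labels Predicted binary labels.
#' @param true_labels True binary labels.
#' @param threshold Optional threshold recorded in the report (metadata only).
#' @param alpha Two-sided significance level for the intervals.
#' @return An object of class `metrics_report`: a list with `counts`
#'   (TP, FP, TN, FN) and one `c(est, lower, upper)` entry per metric.
#' @export
confusion_metrics <- function(pred_labels, true_labels, threshold = NA_real_,
                              alpha = 0.05) {
  pred <- as_binary_labels(pred_labels)
  truth <- as_binary_labels(true_labels)
  if (length(pred) != length(truth)) stop("length mismatch")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  tn <- sum(pred == 0L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  prop <- function(k, n) {
    if (n == 0L) return(c(est = NA_real_, lower = NA_real_, upper = NA_real_))
    c(est = k / n, clopper_pearson(k, n, alpha))
  }
  out <- list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = prop(tp + tn, tp + fp + tn + fn),
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn),
    threshold = threshold
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Thresholded classification metrics (positive event = pCR)\n")
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n", m, v["est"], v["lower"],
                v["upper"]))
  }
  if (!is.na(x$threshold)) cat(sprintf("  threshold: %.3f\n", x$threshold))
  invisible(x)
}

#' Full metrics report for continuous scores
#'
#' Combines AUC (DeLong CI), AP (stratified bootstrap CI) and thresholded
#' confusion metrics into one report.
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold applied to the scores.
#' @param ap_reps,seed Bootstrap settings for the AP interval.
#' @return A `metrics_report` with additional `auc` and `ap` entries.
#' @export
score_metrics <- function(scores, labels, threshold = 0.5, ap_reps = 2000,
                          seed = 1L) {
  labels <- as_binary_labels(labels)
  rep <- confusion_metrics(scores >= threshold, labels, threshold = threshold)
  a <- auc_ci_delong(scores, labels)
  p <- ap_ci_bootstrap(scores, labels, reps = ap_reps, seed = seed)
  rep$auc <- c(est = a$auc, lower = a$ci[1], upper = a$ci[2])
  rep$ap <- c(est = p$ap, lower = p$ci[1], upper = p$ci[2])
  rep
}

#' Relative improvement between two metric values
#'
#' Ratio convention: `100 * (metric_new / metric_ref - 1)`, the convention
#' under which the published model-comparison percentages reproduce from the
#' underlying AUC values.
#'
#' @param metric_ref Reference (baseline) metric, > 0.
#' @param metric_new New metric.
#' @param digits Decimal places in the returned value (default 1, the
#'   reporting precision).
#' @return Percentage change (one decimal by default).
#' @examples
#' relative_improvement(0.792, 0.898)  # 13.4
#' @export
relative_improvement <- function(metric_ref, metric_new, digits = 1) {
  if (any(metric_ref <= 0)) stop("reference metric must be positive")
  round(100 * (metric_new / metric_ref - 1), digits)
}

#' Relative error-rate reduction
#'
#' `100 * (err_ref - err_new) / err_ref`.  Accepts raw fractions or
#' pre-rounded percentages; mixed-convention inputs (a rounded percentage
#' versus a raw count ratio) give slightly different last digits, so callers
#' should state which convention they passed.
#'
#' @param err_ref Reference error rate (fraction or percent), > 0.
#' @param err_new New error rate on the same scale.
#' @param digits Decimal places in the returned value.
#' @return Percentage reduction.
#' @examples
#' error_rate_reduction(8 / 19, 4 / 23)  # 58.7
#' @export
error_rate_reduction <- function(err_ref, err_new, digits = 1) {
  if (any(err_ref <= 0)) stop("reference error rate must be positive")
  round(100 * (err_ref - err_new) / err_ref, digits)
}

# Fisher exact test for a 2x2 table in the doubled-one-tail dialect:
# two-sided p = min(1, 2 * smaller hypergeometric tail at the observed count).
fisher_doubled_one_tail <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  k <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 total
  n <- sum(tab[2, ])   # row-2 total
  q <- sum(tab[, 1])   # column-1 total
  lower <- stats::phyper(k, q, m + n - q, m)
  upper <- 1 - stats::phyper(k - 1, q, m + n - q, m)
  min(1, 2 * min(lower, upper))
}

#' Baseline association test with publication-style dispatch
#'
#' Categorical tables: Pearson chi-square when all expected counts are at
#' least 5 (with Yates' continuity correction for 2x2 tables), otherwise
#' Fisher's exact test; for 2x2 tables the Fisher two-sided p-value is
#' computed as double the smaller one-tailed hypergeometric probability,
#' capped at 1.  Continuous covariates: Student's t-test when both groups
#' pass a Shapiro-Wilk normality pre-check at 0.05, otherwise the
#' Mann-Whitney U test.
#'
#' @param x Either a contingency table/matrix of nonnegative integer counts,
#'   or a numeric vector of a continuous covariate.
#' @param group For continuous `x`: a two-level grouping vector.
#' @return List with `test` (name), `p`, and `statistic` (NA for Fisher).
#' @export
baseline_association_tests <- function(x, group = NULL) {
  if (is.matrix(x) || is.table(x)) {
    tab <- as.matrix(x)
    if (length(tab) == 0L || sum(tab) == 0) stop("empty contingency table")
    if (any(tab < 0) || any(tab != round(tab))) {
      stop("contingency table must hold nonnegative integer counts")
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    is2x2 <- all(dim(tab) == c(2L, 2L))
    if (all(expected >= 5)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = is2x2))
      name <- if (is2x2) "chi-square (Yates)" else "chi-square"
      return(list(test = name, p = ct$p.value,
                  statistic = unname(ct$statistic)))
    }
    if (is2x2) {
      return(list(test = "fisher (doubled one-tail)",
                  p = fisher_doubled_one_tail(tab), statistic = NA_real_))
    }
    return(list(test = "fisher",
                p = stats::fisher.test(tab)$p.value, statistic = NA_real_))
  }
  if (is.null(group)) stop("continuous covariate requires a grouping vector")
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("grouping must have exactly two levels")
  xs <- split(x, g)
  normal <- all(vapply(xs, function(v) {
    length(v) >= 3 && length(unique(v)) > 1 &&
      stats::shapiro.test(v)$p.value > 0.05
  }, logical(1)))
  if (normal) {
    tt <- stats::t.test(xs[[1]], xs[[2]])
    list(test = "t-test", p = tt$p.value, statistic = unname(tt$statistic))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(xs[[1]], xs[[2]]))
    list(test = "mann-whitney", p = wt$p.value,
         statistic = unname(wt$statistic))
  }
}

#' Per-subgroup metrics reports
#'
#' Evaluates the scores separately inside each level of a grouping factor
#' (e.g. molecular subtype or clinical T stage).  Groups missing one class
#' yield a flagged partial report (AUC/AP set to NA) rather than an error.
#'
#' @inheritParams roc_auc
#' @param grouping Factor or character vector assigning each case to a group;
#'   must cover all cases (no NA).
#' @param threshold Classification threshold.
#' @param ap_reps,seed Bootstrap settings forwarded to [score_metrics()].
#' @return Named list of `metrics_report` objects, one per group, each with
#'   a logical `degenerate` flag.
#' @export
subgroup_report <- function(scores, labels, grouping, threshold = 0.5,
                            ap_reps = 500, seed = 1L) {
  labels <- as_binary_labels(labels)
  if (anyNA(grouping)) stop("unknown (NA) group value")
  if (length(grouping) != length(scores)) stop("grouping must cover all cases")
  g <- as.factor(grouping)
  out <- lapply(levels(g), function(lev) {
    i <- which(g == lev)
    if (length(unique(labels[i])) < 2L) {
      rep <- confusion_metrics(scores[i] >= threshold, labels[i],
                               threshold = threshold)
      rep$auc <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      rep$ap <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      rep$degenerate <- TRUE
      return(rep)
    }
    rep <- score_metrics(scores[i], labels[i], threshold = threshold,
                         ap_reps = ap_reps, seed = seed)
    rep$degenerate <- FALSE
    rep
  })
  names(out) <- levels(g)
  out
}

#' Youden-index threshold
#'
#' Threshold maximizing sensitivity + specificity - 1 over the observed
#' scores; ties broken toward the lowest such threshold.
#'
#' @inheritParams roc_auc
#' @return A single threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  thr <- sort(unique(scores))
  youden <- vapply(thr, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1L) / sum(labels == 1L)
    spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
    sens + spec - 1
  }, numeric(1))
  thr[which.max(youden)]
}

# ---- internal helpers -------------------------------------------------------

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (logical or 0/1)")
  }
  labels
}

# Run code under a local RNG seed without touching the global stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
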