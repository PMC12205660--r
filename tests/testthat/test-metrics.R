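test_that("roc_auc matches brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  pair_auc <- function(s, y) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(42)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1)   # rounding forces ties
    expect_equal(roc_auc(s, y), pair_auc(s, y), tolerance = 1e-12)
  }
})

test_that("average_precision matches an exhaustive threshold sweep", {
  expect_equal(average_precision(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)
  # constant scores: a single threshold retrieves everything at precision
  # equal to prevalence
  expect_equal(average_precision(rep(0.2, 10), c(1, rep(0, 9))), 0.1)
  expect_error(average_precision(1:3, c(0, 0, 0)), "positive")
  sweep_ap <- function(s, y) {
    thr <- sort(unique(s), decreasing = TRUE)
    prev_r <- 0
    ap <- 0
    for (t in thr) {
      sel <- s >= t
      r <- sum(y[sel]) / sum(y)
      p <- sum(y[sel]) / sum(sel)
      ap <- ap + (r - prev_r) * p
      prev_r <- r
    }
    ap
  }
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.3)
    if (sum(y) == 0) next
    s <- round(runif(30), 1)
    expect_equal(average_precision(s, y), sweep_ap(s, y), tolerance = 1e-12)
  }
})

test_that("clopper_pearson is the exact tail-inversion interval", {
  ci <- clopper_pearson(8, 8)
  expect_equal(unname(ci["lower"]), 0.025^(1 / 8), tolerance = 1e-12)
  expect_equal(round(unname(ci["lower"]), 3), 0.631)
  expect_equal(unname(ci["upper"]), 1)
  expect_equal(unname(clopper_pearson(0, 5)["lower"]), 0)
  expect_error(clopper_pearson(1, 0), "trials")
  # oracle: invert the binomial tails numerically
  k <- 5; n <- 10
  lower <- uniroot(function(p) 1 - pbinom(k - 1, n, p) - 0.025,
                   c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  upper <- uniroot(function(p) pbinom(k, n, p) - 0.025,
                   c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  ci <- clopper_pearson(k, n)
  expect_equal(unname(ci["lower"]), lower, tolerance = 1e-6)
  expect_equal(unname(ci["upper"]), upper, tolerance = 1e-6)
})

test_that("delong_test is degenerate on identical scores and agrees with pROC", {
  set.seed(3)
  y <- rbinom(50, 1, 0.4)
  s <- rnorm(50) + y
  d <- delong_test(s, s, y)
  expect_equal(d$diff, 0)
  expect_equal(d$p, 1)
  skip_if_not_installed("pROC")
  s2 <- rnorm(50) + 0.5 * y
  d <- delong_test(s, s2, y)
  pr <- pROC::roc.test(pROC::roc(y, s, quiet = TRUE),
                       pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(d$p, pr$p.value, tolerance = 1e-8)
  ci <- auc_ci_delong(s, y)
  pci <- as.numeric(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                 method = "delong"))
  expect_equal(ci$auc, pci[2], tolerance = 1e-10)
  expect_equal(ci$ci[1], max(0, pci[1]), tolerance = 1e-8)
})

test_that("confusion_metrics reproduces published prospective proportions", {
  # 37 of 41 non-pCR and 19 of 23 pCR classified correctly
  pred <- c(rep(TRUE, 19), rep(FALSE, 4), rep(FALSE, 37), rep(TRUE, 4))
  truth <- c(rep(TRUE, 23), rep(FALSE, 41))
  cm <- confusion_metrics(pred, truth)
  expect_equal(round(unname(cm$sensitivity["est"]), 3), 0.826)
  expect_equal(round(unname(cm$specificity["est"]), 3), 0.902)
  expect_true(cm$sensitivity["lower"] <= cm$sensitivity["est"])
  expect_true(cm$sensitivity["upper"] >= cm$sensitivity["est"])
  perfect <- confusion_metrics(truth, truth)
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(unname(perfect[[m]]["est"]), 1)
  }
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("relative improvement and error-rate reduction use the ratio convention", {
  expect_equal(relative_improvement(0.792, 0.898), 13.4)
  expect_equal(relative_improvement(0.544, 0.898), 65.1)
  expect_equal(relative_improvement(0.7, 0.7), 0)
  expect_error(relative_improvement(0, 0.5), "positive")
  expect_equal(error_rate_reduction(8 / 19, 4 / 23), 58.7)
  expect_equal(error_rate_reduction(26.7, 9.8), 63.3)
  expect_equal(error_rate_reduction(0.3, 0.3), 0)
  expect_error(error_rate_reduction(0, 0.1), "positive")
})

test_that("baseline tests dispatch per the published rule set", {
  # identical row distributions: Fisher dialect capped near 1
  tab <- matrix(c(3, 3, 2, 2), 2)
  r <- baseline_association_tests(tab)
  expect_match(r$test, "fisher")
  expect_equal(r$p, 1)
  # doubled-one-tail Fisher equals hypergeometric enumeration
  tab <- matrix(c(1, 6, 7, 2), 2)
  r <- baseline_association_tests(tab)
  k <- tab[1, 1]
  lower <- sum(dhyper(0:k, sum(tab[, 1]), sum(tab[, 2]), sum(tab[1, ])))
  upper <- sum(dhyper(k:sum(tab[1, ]), sum(tab[, 1]), sum(tab[, 2]),
                      sum(tab[1, ])))
  expect_equal(r$p, min(1, 2 * min(lower, upper)), tolerance = 1e-12)
  # Yates-corrected chi-square equals the textbook formula
  tab <- matrix(c(30, 10, 20, 25), 2)
  r <- baseline_association_tests(tab)
  expect_equal(r$test, "chi-square (Yates)")
  ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - ex) - 0.5)^2 / ex)
  expect_equal(r$statistic, stat, tolerance = 1e-10)
  expect_equal(r$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-10)
  # continuous dispatch: heavy-tailed data routes to Mann-Whitney
  set.seed(1)
  x <- c(rnorm(30), rnorm(30, 0.5))
  g <- rep(c("a", "b"), each = 30)
  expect_equal(baseline_association_tests(x, g)$test, "t-test")
  xe <- exp(c(rnorm(30, sd = 2), rnorm(30, 1, 2)))
  expect_equal(baseline_association_tests(xe, g)$test, "mann-whitney")
  expect_error(baseline_association_tests(matrix(numeric(0), 0, 0)), "empty")
})

test_that("subgroup reports aggregate and flag degenerate groups", {
  set.seed(5)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  overall <- score_metrics(s, y, threshold = 0.5, ap_reps = 100)
  one <- subgroup_report(s, y, rep("all", 60), threshold = 0.5,
                         ap_reps = 100)
  expect_equal(one$all$auc, overall$auc)
  expect_equal(one$all$counts, overall$counts)
  g <- c(rep("A", 50), rep("B", 10))
  y2 <- y
  y2[51:60] <- 0   # group B has no positives
  rep2 <- subgroup_report(s, y2, g, threshold = 0.5, ap_reps = 50)
  expect_true(rep2$B$degenerate)
  expect_true(is.na(rep2$B$auc["est"]))
  expect_false(is.na(rep2$B$specificity["est"]))
  expect_error(subgroup_report(s, y, c(rep("A", 59), NA)), "unknown")
})

test_that("youden_threshold maximizes sensitivity + specificity - 1", {
  s <- c(0.1, 0.2, 0.6, 0.7, 0.9)
  y <- c(0, 0, 1, 1, 1)
  thr <- youden_threshold(s, y)
  expect_equal(thr, 0.6)
  expect_true(all(s[y == 1] >= thr))
})
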