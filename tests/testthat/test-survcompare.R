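test_that("km_estimate follows the hand-computed product limit", {
  km <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # duplicating every subject leaves the curve unchanged
  t <- c(2, 4, 4, 7, 9)
  e <- c(1, 0, 1, 1, 0)
  km1 <- km_estimate(t, e)
  km2 <- km_estimate(rep(t, 2), rep(e, 2))
  expect_equal(km1$surv, km2$surv, tolerance = 1e-12)
  expect_equal(km1$time, km2$time)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("pooled risk sets equal the sum of group risk sets", {
  set.seed(2)
  tA <- rexp(40, 0.1); eA <- rbinom(40, 1, 0.7)
  tB <- rexp(30, 0.2); eB <- rbinom(30, 1, 0.7)
  pooled <- km_estimate(c(tA, tB), c(eA, eB))
  for (i in seq_along(pooled$time)) {
    tt <- pooled$time[i]
    expect_equal(pooled$n_risk[i], sum(tA >= tt) + sum(tB >= tt))
  }
})

test_that("logrank_test is null on identical groups and detects planted hazard", {
  t <- c(1, 3, 5, 7, 9)
  e <- c(1, 1, 0, 1, 0)
  r <- logrank_test(t, e, t, e)
  expect_equal(r$chisq, 0, tolerance = 1e-10)
  expect_equal(r$p, 1, tolerance = 1e-10)
  expect_error(logrank_test(numeric(0), logical(0), t, e), "nonempty")
  # planted hazard ratio 2, moderate n: should reject at 0.05
  set.seed(11)
  tA <- rexp(250, 0.1); tB <- rexp(250, 0.2)
  cA <- runif(250, 0, 30); cB <- runif(250, 0, 30)
  r <- logrank_test(pmin(tA, cA), tA <= cA, pmin(tB, cB), tB <= cB)
  expect_lt(r$p, 0.001)
})

test_that("cox_univariate recovers a planted log-hazard ratio", {
  set.seed(4)
  n <- 800
  x <- rnorm(n)
  beta <- -0.35
  tt <- rexp(n, 0.05 * exp(beta * x))
  cc <- runif(n, 0, 40)
  r <- cox_univariate(pmin(tt, cc), tt <= cc, x)
  expect_equal(r$log_hr, beta, tolerance = 0.12)
  expect_true(r$ci[1] <= r$hazard_ratio && r$hazard_ratio <= r$ci[2])
  expect_lt(r$p_wald, 0.001)
  expect_lt(r$p_likelihood_ratio, 0.001)
  expect_error(cox_univariate(tt, tt <= cc, rep(1, n)), "constant")
  # binary covariate agrees in direction with the log-rank comparison
  g <- rbinom(n, 1, 0.5)
  t2 <- rexp(n, 0.05 * exp(0.7 * g))
  r2 <- cox_univariate(pmin(t2, cc), t2 <= cc, g)
  expect_gt(r2$hazard_ratio, 1)
})

test_that("stratify_by_score supports median and fixed rules", {
  s <- c(0.1, 0.4, 0.6, 0.9)
  st <- stratify_by_score(s)
  expect_equal(as.character(st$group), c("low", "low", "high", "high"))
  st2 <- stratify_by_score(s, "fixed_threshold", threshold = 0.8)
  expect_equal(sum(st2$group == "high"), 1)
  expect_error(stratify_by_score(s, "fixed_threshold", threshold = 2),
               "range")
})
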