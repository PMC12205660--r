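test_that("clinical encoding is complete and screening honours alpha", {
  co <- generate_cohort(tiny_phantom(250, seed = 41))
  clin <- cohort_clinical(co)
  X <- encode_clinical(clin)
  expect_false(anyNA(X))
  expect_true(all(c("er", "pr", "her2", "subtype_her2", "age") %in%
                    colnames(X)))
  labs <- clin$pcr
  # the planted subtype effect surfaces receptor-status factors
  sel <- suppressWarnings(screen_clinical_factors(X, labs, alpha = 0.05))
  expect_true(any(c("her2", "subtype_her2", "er", "pr",
                    "subtype_tnbc") %in% sel))
  # alpha = 1 passes every factor through both stages
  sel_all <- suppressWarnings(screen_clinical_factors(X, labs, alpha = 1))
  expect_setequal(sel_all, colnames(X))
  expect_error(screen_clinical_factors(X[1:3, ], labs[1:3]), "per class")
})

test_that("perfect separation is flagged and retained, not dropped", {
  set.seed(2)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 2 - 1 + rnorm(n, 0, 1e-4),   # separates perfectly
             noise = rnorm(n))
  expect_warning(sel <- screen_clinical_factors(X, y, alpha = 0.05),
                 "separation")
  expect_true("sep" %in% sel)
  expect_true(attr(sel, "separated"))
})

test_that("fit_svm separates separable data and errors on one class", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, -3), 20), matrix(rnorm(40, 3), 20))
  y <- rep(c(0, 1), each = 20)
  m <- fit_svm(X, y, grid = list(cost = 1, gamma = NA), folds = 0)
  pred <- svm_scores(m, X) >= 0.5
  expect_equal(mean(pred == y), 1)
  expect_error(fit_svm(X, rep(1, 40)), "single-class")
  # duplicated identical column: decision function unchanged up to tolerance
  m2 <- fit_svm(cbind(X, X[, 1]), y, grid = list(cost = 1, gamma = NA),
                folds = 0)
  s1 <- svm_scores(m, X)
  s2 <- svm_scores(m2, cbind(X, X[, 1]))
  expect_gt(cor(s1, s2), 0.99)
})

test_that("label permutation drives SVM CV performance to chance", {
  set.seed(9)
  X <- matrix(rnorm(60 * 5), 60)
  y <- rbinom(60, 1, 0.5)
  aucs <- vapply(1:60, function(i) {
    yp <- sample(y)
    fold <- rep_len(1:3, 60)
    mean(vapply(1:3, function(f) {
      m <- e1071::svm(X[fold != f, ], factor(yp[fold != f]),
                      probability = TRUE)
      roc_auc(svm_scores(m, X[fold == f, ]), yp[fold == f])
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the GA is elitist, penalized and deterministic", {
  set.seed(12)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y + rnorm(n, 0, 0.5), matrix(rnorm(n * 6), n))
  ga <- ga_config(population_size = 12, generations = 6, seed = 7)
  sel1 <- ga_select_features(X, NULL, y, ga, folds = 2)
  sel2 <- ga_select_features(X, NULL, y, ga, folds = 2)
  expect_identical(as.integer(sel1), as.integer(sel2))
  fit_hist <- attr(sel1, "fitness")
  expect_true(all(diff(fit_hist) >= -1e-12))   # elitism: nondecreasing
  # a huge per-feature penalty collapses the selection
  ga_pen <- ga_config(population_size = 12, generations = 6, seed = 7,
                      penalty_per_feature = 10)
  sel_pen <- ga_select_features(X, NULL, y, ga_pen, folds = 2)
  expect_lte(length(sel_pen), 1)
  # generations = 0 still returns the best of the seeded initial population
  ga0 <- ga_config(population_size = 12, generations = 0, seed = 7)
  sel0a <- ga_select_features(X, NULL, y, ga0, folds = 2)
  sel0b <- ga_select_features(X, NULL, y, ga0, folds = 2)
  expect_identical(as.integer(sel0a), as.integer(sel0b))
})

test_that("clinical and combined models fit end to end", {
  co <- generate_cohort(tiny_phantom(120, seed = 43))
  clin <- cohort_clinical(co)
  labs <- clin$pcr
  cm <- fit_clinical_model(clin, labs, folds = 3, seed = 1)
  expect_gt(roc_auc(cm$scores, labs), 0.6)   # subtype carries real signal
  set.seed(4)
  deep <- cbind(matrix(rnorm(120 * 10), 120), labs + rnorm(120, 0, 0.8))
  comb <- fit_combined_model(deep, clin, labs,
                             ga = ga_config(population_size = 10,
                                            generations = 4, seed = 3),
                             folds = 3, seed = 1)
  expect_true(length(comb$selected_deep) >= 1)
  expect_gt(roc_auc(comb$scores, labs), 0.6)
})
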