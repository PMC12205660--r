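#' Encode clinical records as a numeric design matrix
#'
#' Binary indicators for ER/PR/HER2/Ki-67/menopause, ordinal clinical T
#' stage, one-hot molecular subtype, and standardized age and baseline long
#' diameter.  No missing values are permitted after encoding.
#'
#' @param clinical Data frame as returned by [cohort_clinical()].
#' @param standardize Standardize the continuous columns.
#' @return Numeric matrix (patients x encoded features).
#' @export
encode_clinical <- function(clinical, standardize = TRUE) {
  pos <- function(x) as.numeric(x == "positive")
  m <- cbind(
    age = clinical$age,
    ld_mm = clinical$ld_mm,
    menopause_post = as.numeric(clinical$menopause == "post"),
    t_stage_34 = as.numeric(clinical$t_stage == "T3-T4"),
    er = pos(clinical$er), pr = pos(clinical$pr),
    her2 = pos(clinical$her2), ki67 = pos(clinical$ki67),
    subtype_her2 = as.numeric(clinical$subtype == "HER2+"),
    subtype_tnbc = as.numeric(clinical$subtype == "HR-/HER2-")
  )
  if (anyNA(m)) stop("missing values after clinical encoding")
  if (standardize) {
    for (j in c("age", "ld_mm")) {
      s <- stats::sd(m[, j])
      m[, j] <- (m[, j] - mean(m[, j])) / if (s > 0) s else 1
    }
  }
  m
}

# Ridge-penalized logistic fit by IRLS; Wald p-values from the penalized
# information.  Fallback when ML logistic regression separates perfectly.
ridge_logistic <- function(X, y, lambda = 1e-2, iter = 50) {
  X <- cbind(1, X)
  beta <- numeric(ncol(X))
  for (it in seq_len(iter)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    Wd <- pmax(p * (1 - p), 1e-8)
    H <- crossprod(X * Wd, X) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  list(coef = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

# Wald p-value of a single covariate in a logistic model, with separation
# detection and penalized fallback (flagged).
logistic_p <- function(X, y) {
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(fit$fitted.values > 1 - 1e-8 & y == 1) &&
      all(fit$fitted.values[y == 1] > 1 - 1e-8)
  if (separated) {
    pr <- ridge_logistic(as.matrix(X), y)
    return(list(p = pr$p[-1], separated = TRUE))
  }
  cf <- summary(fit)$coefficients
  list(p = cf[-1, 4], separated = FALSE)
}

#' Screen clinical factors by two-stage logistic regression
#'
#' Univariate logistic regression per factor; factors with p < `alpha`
#' enter a joint multivariate logistic model, and those with multivariate
#' p < `alpha` are returned (in the deterministic column order of the
#' encoded table).  A factor causing perfect separation is flagged and
#' retained through a ridge-penalized fit rather than silently dropped.
#'
#' @param clinical_matrix Encoded clinical matrix ([encode_clinical()]).
#' @param labels Binary outcome (pCR).
#' @param alpha Significance level for both stages (default 0.05).
#' @return Character vector of selected factor names, with attributes
#'   `univariate_p`, `multivariate_p` and `separated`.
#' @export
screen_clinical_factors <- function(clinical_matrix, labels, alpha = 0.05) {
  y <- as_binary_labels(labels)
  if (sum(y) < 2L || sum(1 - y) < 2L) stop("need >= 2 cases per class")
  nm <- colnames(clinical_matrix)
  separated_any <- FALSE
  separated_factors <- character(0)
  # univariate stage: likelihood-ratio p-values (better calibrated than
  # Wald at moderate n); multivariate stage below uses per-coefficient Wald
  uni_p <- vapply(nm, function(j) {
    x <- clinical_matrix[, j, drop = FALSE]
    if (stats::sd(x) == 0) return(1)
    r <- logistic_p(x, y)
    if (r$separated) {
      warning(sprintf("perfect separation for factor %s: flagged and retained (penalized fit)", j))
      separated_any <<- TRUE
      separated_factors <<- c(separated_factors, j)
      return(r$p[[1]])
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                  lower.tail = FALSE)
  }, numeric(1))
  stage1 <- nm[uni_p < alpha | nm %in% separated_factors]
  multi_p <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (length(stage1) == 0L) {
    selected <- character(0)
  } else if (length(stage1) == 1L) {
    selected <- stage1
    multi_p[stage1] <- uni_p[stage1]
  } else {
    r <- logistic_p(clinical_matrix[, stage1, drop = FALSE], y)
    if (r$separated) separated_any <- TRUE
    multi_p[stage1] <- r$p
    selected <- stage1[r$p < alpha]
  }
  # a separating factor is flagged and retained, never silently dropped
  selected <- nm[nm %in% union(selected, separated_factors)]
  structure(selected, univariate_p = uni_p, multivariate_p = multi_p,
            separated = separated_any, separated_factors = separated_factors)
}

#' Fit an RBF-kernel SVM with probability outputs
#'
#' Support vector machine with grid-searched `(cost, gamma)` by stratified
#' k-fold cross-validated AUC.  The same routine serves the clinical-only
#' model, the combined model, and the fitness evaluations of the genetic
#' algorithm.
#'
#' @param features Numeric matrix (standardized by `e1071::svm` scaling).
#' @param labels Binary outcome.
#' @param grid Named list with vectors `cost` and `gamma` (`gamma = NA`
#'   uses the 1/ncol default).
#' @param folds CV folds for the grid search (skipped for a 1-point grid).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param seed Seed for fold assignment.
#' @return List of class `svm_model`: `fit`, `best` (chosen
#'   hyperparameters), `cv_auc` (grid x fold matrix or NULL).
#' @export
fit_svm <- function(features, labels, grid = list(cost = c(0.5, 1, 4),
                                                  gamma = NA),
                    folds = 5L, kernel = "radial", seed = 1L) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("single-class input")
  features <- as.matrix(features)
  combos <- expand.grid(grid)
  combos$gamma[is.na(combos$gamma)] <- 1 / ncol(features)
  cv_auc <- NULL
  best <- 1L
  if (nrow(combos) > 1L && folds >= 2L) {
    fold <- stratified_folds(y, folds, seed)
    cv_auc <- matrix(NA_real_, nrow(combos), folds)
    for (r in seq_len(nrow(combos))) {
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
        m <- e1071::svm(features[tr, , drop = FALSE], factor(y[tr]),
                        kernel = kernel, cost = combos$cost[r],
                        gamma = combos$gamma[r], probability = TRUE,
                        scale = apply(features, 2, stats::sd) > 0)
        sc <- svm_scores(m, features[!tr, , drop = FALSE])
        cv_auc[r, f] <- roc_auc(sc, y[!tr])
      }
    }
    best <- which.max(rowMeans(cv_auc, na.rm = TRUE))
  }
  fit <- e1071::svm(features, factor(y), kernel = kernel,
                    cost = combos$cost[best], gamma = combos$gamma[best],
                    probability = TRUE,
                    scale = apply(features, 2, stats::sd) > 0)
  structure(list(fit = fit, best = combos[best, , drop = FALSE],
                 cv_auc = cv_auc), class = "svm_model")
}

#' Positive-class probability from a fitted SVM
#'
#' @param fit A [fit_svm()] result (or raw `e1071::svm` fit with
#'   probability model).
#' @param features Feature matrix to score.
#' @return Numeric vector of positive-class probabilities.
#' @export
svm_scores <- function(fit, features) {
  if (inherits(fit, "svm_model")) fit <- fit$fit
  pr <- attr(stats::predict(fit, features, probability = TRUE),
             "probabilities")
  pr[, "1"]
}

#' Configuration of the genetic-algorithm feature selector
#'
#' @param population_size Even population size.
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Probabilities in \[0, 1\].
#' @param penalty_per_feature Fitness penalty per selected feature.
#' @param seed Seed for the whole GA run.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, generations = 30L,
                      crossover_rate = 0.8, mutation_rate = 0.02,
                      penalty_per_feature = 0.002, seed = 1L) {
  stopifnot(population_size %% 2 == 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 fitness = "cv_auc_svm",
                 penalty_per_feature = penalty_per_feature,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm selection of deep features
#'
#' Binary-chromosome GA over the deep-feature columns.  Fitness of a
#' chromosome is the mean stratified k-fold AUC of an SVM trained on the
#' selected deep features concatenated with the clinical features (the
#' clinical block always participates, so selection is clinically
#' conditioned), minus `penalty_per_feature` per selected feature.
#' Tournament selection (size 3), uniform crossover, bit-flip mutation and
#' elitism of 2; the best-ever chromosome is returned, so an all-zero final
#' population still yields a valid selection.
#'
#' @param deep_features Matrix (patients x deep features).
#' @param clinical_features Matrix appended to every fitness evaluation
#'   (may have zero columns).
#' @param labels Binary outcome.
#' @param ga A [ga_config()].
#' @param folds CV folds inside the fitness function.
#' @param svm_cost,svm_gamma Fixed SVM hyperparameters for fitness scoring.
#' @return Integer vector of selected deep-feature column indices, with
#'   attributes `fitness` (best per generation) and `best_fitness`.
#' @export
ga_select_features <- function(deep_features, clinical_features = NULL,
                               labels, ga = ga_config(), folds = 3L,
                               svm_cost = 1, svm_gamma = NA) {
  y <- as_binary_labels(labels)
  deep_features <- as.matrix(deep_features)
  p <- ncol(deep_features)
  if (p == 0L) stop("deep_features must be nonempty")
  if (is.null(clinical_features)) {
    clinical_features <- matrix(numeric(0), nrow(deep_features), 0)
  }
  fold <- stratified_folds(y, folds, ga$seed)
  memo <- new.env(parent = emptyenv())
  fitness <- function(chrom) {
    key <- paste0("k", paste(which(chrom > 0), collapse = ","))
    if (!is.null(memo[[key]])) return(memo[[key]])
    sel <- which(chrom > 0)
    X <- cbind(deep_features[, sel, drop = FALSE], clinical_features)
    val <- if (ncol(X) == 0L) {
      -Inf
    } else {
      gamma <- if (is.na(svm_gamma)) 1 / ncol(X) else svm_gamma
      aucs <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
          return(NA_real_)
        }
        m <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "radial", cost = svm_cost, gamma = gamma,
                        probability = TRUE,
                        scale = apply(X, 2, stats::sd) > 0)
        roc_auc(svm_scores(m, X[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE) - ga$penalty_per_feature * length(sel)
    }
    memo[[key]] <- val
    val
  }
  withr_seed(ga$seed, {
    pop <- matrix(stats::rbinom(ga$population_size * p, 1, 0.3),
                  ga$population_size, p)
    fit <- apply(pop, 1, fitness)
    best_chrom <- pop[which.max(fit), ]
    best_fit <- max(fit)
    gen_best <- numeric(0)
    for (g in seq_len(ga$generations)) {
      elite_idx <- order(fit, decreasing = TRUE)[1:2]
      newpop <- pop[elite_idx, , drop = FALSE]
      while (nrow(newpop) < ga$population_size) {
        pick <- function() {
          cand <- sample(ga$population_size, 3)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        if (stats::runif(1) < ga$crossover_rate) {
          swap <- stats::runif(p) < 0.5
          tmp <- p1[swap]
          p1[swap] <- p2[swap]
          p2[swap] <- tmp
        }
        flip1 <- stats::runif(p) < ga$mutation_rate
        flip2 <- stats::runif(p) < ga$mutation_rate
        p1[flip1] <- 1 - p1[flip1]
        p2[flip2] <- 1 - p2[flip2]
        newpop <- rbind(newpop, p1, p2)
      }
      pop <- newpop[seq_len(ga$population_size), , drop = FALSE]
      fit <- apply(pop, 1, fitness)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_chrom <- pop[which.max(fit), ]
      }
      gen_best <- c(gen_best, best_fit)
    }
    structure(which(best_chrom > 0), fitness = gen_best,
              best_fitness = best_fit)
  })
}

#' Clinical-only and combined (deep + clinical) SVM models
#'
#' `fit_clinical_model` screens the encoded clinical factors and fits an
#' SVM on the selected ones (all factors if none pass screening, flagged).
#' `fit_combined_model` GA-selects deep features conditioned on the
#' clinical block and fits the combined SVM on the selected deep features
#' plus the screened clinical features.
#'
#' @param clinical Data frame from [cohort_clinical()] (the `pcr` column is
#'   ignored as a predictor).
#' @param labels Binary outcome.
#' @param deep_features Matrix of model embeddings
#'   (`predict(model, cohort, type = "embedding")`).
#' @param alpha Screening significance level.
#' @param ga A [ga_config()].
#' @param grid,folds,seed Forwarded to [fit_svm()].
#' @return List with the fitted `svm_model`, the selected columns and a
#'   `score` function mapping new feature rows to probabilities.
#' @export
fit_clinical_model <- function(clinical, labels, alpha = 0.05,
                               grid = list(cost = c(0.5, 1, 4), gamma = NA),
                               folds = 5L, seed = 1L) {
  X <- encode_clinical(clinical)
  sel <- suppressWarnings(screen_clinical_factors(X, labels, alpha))
  used <- if (length(sel)) sel else colnames(X)
  svm <- fit_svm(X[, used, drop = FALSE], labels, grid, folds, seed = seed)
  list(svm = svm, selected = sel, used = used,
       scores = svm_scores(svm, X[, used, drop = FALSE]),
       score = function(new_clinical) {
         svm_scores(svm, encode_clinical(new_clinical)[, used, drop = FALSE])
       })
}

#' @rdname fit_clinical_model
#' @export
fit_combined_model <- function(deep_features, clinical, labels,
                               alpha = 0.05, ga = ga_config(),
                               grid = list(cost = c(0.5, 1, 4), gamma = NA),
                               folds = 5L, seed = 1L) {
  X <- encode_clinical(clinical)
  sel_clin <- suppressWarnings(screen_clinical_factors(X, labels, alpha))
  used_clin <- if (length(sel_clin)) sel_clin else colnames(X)
  Xc <- X[, used_clin, drop = FALSE]
  deep_features <- as.matrix(deep_features)
  # standardize deep features once for the GA and the final fit
  Zd <- scale(deep_features)
  Zd[, attr(Zd, "scaled:scale") == 0] <- 0
  sel_deep <- ga_select_features(Zd, Xc, labels, ga)
  comb <- cbind(Zd[, sel_deep, drop = FALSE], Xc)
  svm <- fit_svm(comb, labels, grid, folds, seed = seed)
  list(svm = svm, selected_deep = as.integer(sel_deep),
       selected_clinical = used_clin,
       center = attr(Zd, "scaled:center"), scale = attr(Zd, "scaled:scale"),
       scores = svm_scores(svm, comb))
}
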