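#' Configuration of a full reference experiment
#'
#' Bundles the per-stage configurations into one reproducible experiment
#' description.  `global_seed` is propagated into every stage config that
#' does not override it.
#'
#' @param phantom A [phantom_config()].
#' @param preproc A [preproc_config()].
#' @param model An [sti_config()].
#' @param ga A [ga_config()].
#' @param variants Model variants to train (subset of [sti_variants()]).
#' @param evaluation List with `alpha` (screening significance) and
#'   `bootstrap_reps` (AP interval).
#' @param survival_rule Stratification rule for the survival stage.
#' @param train_fraction Stratified train fraction of the cohort split.
#' @param with_fusion Also fit the clinical and combined models.
#' @param with_survival Run the survival stage.
#' @param output_dir Directory for artifacts (NULL: return-only).
#' @param global_seed Master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(n_patients = 200),
                              preproc = preproc_config(),
                              model = sti_config(),
                              ga = ga_config(),
                              variants = sti_variants(),
                              evaluation = list(alpha = 0.05,
                                                bootstrap_reps = 500),
                              survival_rule = "median_split",
                              train_fraction = 0.8,
                              with_fusion = TRUE,
                              with_survival = TRUE,
                              output_dir = NULL,
                              global_seed = 1L) {
  phantom$seed <- as.integer(global_seed)
  model$seed <- as.integer(global_seed)
  ga$seed <- as.integer(global_seed)
  structure(list(phantom = phantom, preproc = preproc, model = model,
                 ga = ga, variants = variants, evaluation = evaluation,
                 survival_rule = survival_rule,
                 train_fraction = train_fraction,
                 with_fusion = with_fusion, with_survival = with_survival,
                 output_dir = output_dir,
                 global_seed = as.integer(global_seed)),
            class = "experiment_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("experiment stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the reference end-to-end synthetic experiment
#'
#' Generates a phantom cohort, splits it stratified into train/validation,
#' segments habitats, trains the configured model variants on shared
#' encoder features, evaluates them (overall metrics, DeLong comparisons
#' against the full STI model, subgroup reports), optionally fits the
#' clinical and combined models, and stratifies validation survival by STI
#' score.  Fully reproducible under `global_seed`.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return A report list with elements `split`, `models`, `metrics`,
#'   `delong`, `subgroups`, `fusion`, `survival`, `summary` (flat,
#'   JSON-ready metric block).
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- run_stage("generate", {
    say("generating cohort (n = %d)", config$phantom$n_patients)
    generate_cohort(config$phantom)
  })
  labels <- cohort_labels(cohort)
  split <- run_stage("split", {
    fold <- stratified_folds(labels, round(1 / (1 - config$train_fraction)),
                             config$global_seed)
    list(train = which(fold != 1L), test = which(fold == 1L))
  })
  feats <- run_stage("preprocess+segment+encode", {
    say("preprocessing, habitat segmentation and encoding")
    params0 <- sti_init_params(config$model)
    extract_features(cohort, params0, config$model, config$preproc)
  })
  trained <- run_stage("train", {
    out <- list()
    for (v in config$variants) {
      say("training variant %s", v)
      m <- sti_fit(cohort[split$train], config$model, variant = v,
                   preproc = config$preproc,
                   features = feats[split$train], cv = FALSE)
      out[[v]] <- list(model = m,
                       pred = predict(m, cohort[split$test],
                                      features = feats[split$test]))
    }
    out
  })
  models <- lapply(trained, `[[`, "model")
  predictions <- lapply(trained, `[[`, "pred")
  test_labels <- labels[split$test]
  metrics <- run_stage("evaluate", {
    lapply(predictions, function(pr) {
      score_metrics(pr$score, test_labels, threshold = pr$threshold[1],
                    ap_reps = config$evaluation$bootstrap_reps,
                    seed = config$global_seed)
    })
  })
  delong <- run_stage("delong", {
    ref <- config$variants[length(config$variants)]
    comps <- setdiff(names(predictions), ref)
    out <- lapply(comps, function(v) {
      d <- delong_test(predictions[[ref]]$score, predictions[[v]]$score,
                       test_labels)
      d$improvement_pct <- relative_improvement(d$aucB, d$aucA)
      d
    })
    names(out) <- paste0(ref, "_vs_", comps)
    out
  })
  subgroups <- run_stage("subgroups", {
    v <- config$variants[length(config$variants)]
    clin <- cohort_clinical(cohort[split$test])
    list(subtype = subgroup_report(predictions[[v]]$score, test_labels,
                                   clin$subtype,
                                   threshold = predictions[[v]]$threshold[1]),
         t_stage = subgroup_report(predictions[[v]]$score, test_labels,
                                   clin$t_stage,
                                   threshold = predictions[[v]]$threshold[1]))
  })
  fusion <- NULL
  if (config$with_fusion) {
    fusion <- run_stage("fusion", {
      say("clinical and combined models")
      v <- config$variants[length(config$variants)]
      clin_train <- cohort_clinical(cohort[split$train])
      clin_test <- cohort_clinical(cohort[split$test])
      cm <- fit_clinical_model(clin_train, labels[split$train],
                               alpha = config$evaluation$alpha,
                               seed = config$global_seed)
      emb_train <- predict(models[[v]], cohort[split$train],
                           type = "embedding",
                           features = feats[split$train])
      emb_test <- predict(models[[v]], cohort[split$test],
                          type = "embedding", features = feats[split$test])
      comb <- fit_combined_model(emb_train, clin_train, labels[split$train],
                                 alpha = config$evaluation$alpha,
                                 ga = config$ga, seed = config$global_seed)
      # score the held-out split
      Xc_test <- encode_clinical(clin_test)[, comb$selected_clinical,
                                            drop = FALSE]
      Zd_test <- sweep(sweep(emb_test, 2, comb$center), 2,
                       ifelse(comb$scale == 0, 1, comb$scale), "/")
      comb_test <- cbind(Zd_test[, comb$selected_deep, drop = FALSE],
                         Xc_test)
      list(clinical = cm,
           clinical_test_auc = roc_auc(cm$score(clin_test), test_labels),
           combined = comb,
           combined_test_auc = roc_auc(svm_scores(comb$svm, comb_test),
                                       test_labels))
    })
  }
  surv <- NULL
  if (config$with_survival) {
    surv <- run_stage("survival", {
      v <- config$variants[length(config$variants)]
      survival_by_score(predictions[[v]]$score,
                        cohort_survival(cohort[split$test]),
                        rule = config$survival_rule)
    })
  }
  summary <- list(
    n_train = length(split$train), n_test = length(split$test),
    pcr_rate = mean(labels),
    auc = vapply(metrics, function(m) unname(m$auc["est"]), numeric(1)),
    ap = vapply(metrics, function(m) unname(m$ap["est"]), numeric(1)),
    sensitivity = vapply(metrics, function(m) {
      unname(m$sensitivity["est"])
    }, numeric(1)),
    specificity = vapply(metrics, function(m) {
      unname(m$specificity["est"])
    }, numeric(1))
  )
  if (!is.null(surv)) {
    summary$logrank_p_rfs <- surv$rfs$logrank$p
    summary$logrank_p_os <- surv$os$logrank$p
    summary$cox_hr_rfs <- surv$rfs$cox$hazard_ratio
    summary$cox_hr_os <- surv$os$cox$hazard_ratio
  }
  if (!is.null(fusion)) {
    summary$clinical_auc <- fusion$clinical_test_auc
    summary$combined_auc <- fusion$combined_test_auc
  }
  report <- list(split = split, models = models, predictions = predictions,
                 metrics = metrics, delong = delong, subgroups = subgroups,
                 fusion = fusion, survival = surv, summary = summary,
                 config = config)
  if (!is.null(config$output_dir)) {
    run_stage("write", {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      for (v in names(predictions)) {
        utils::write.csv(predictions[[v]],
                         file.path(config$output_dir,
                                   sprintf("predictions_%s.csv", v)),
                         row.names = FALSE)
      }
      jsonlite::write_json(summary,
                           file.path(config$output_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  report
}
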