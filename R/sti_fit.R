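# Fitting, prediction and explanation of the spatiotemporal interaction
# model.  The shared conv encoder is applied once per region patch and its
# global-average-pool features are cached; by default only the projection,
# attention and classifier parameters are trained on top (the encoder stays
# at its seeded random initialization), while `layerwise_unfreeze` gradually
# fine-tunes the conv stages from the top down.

# Habitat segmentation + preprocessing + encoder features for one case.
case_features <- function(case, params, config, preproc,
                          habitat_seed = config$seed,
                          keep_patches = FALSE) {
  habs <- segment_case_habitats(case, K = config$K, seed = habitat_seed)
  patches <- suppressWarnings(preprocess_case(case, habs, preproc))
  feats <- list()
  for (tp in c("T0", "T1")) {
    G <- t(vapply(patches[[tp]], function(p) {
      encoder_forward(p, params, config)$g
    }, numeric(utils::tail(config$encoder_channels, 1))))
    feats[[tp]] <- G
  }
  if (keep_patches) feats$patches <- patches
  feats
}

# Features for every case of a cohort (list parallel to the cohort).
extract_features <- function(cohort, params, config,
                             preproc = preproc_config(),
                             keep_patches = FALSE) {
  lapply(cohort, case_features, params = params, config = config,
         preproc = preproc, keep_patches = keep_patches)
}

# Re-encode the conv features of cached patches (used once conv stages are
# being fine-tuned and the frozen-feature cache goes stale).
refresh_features <- function(feats, params, config) {
  lapply(feats, function(f) {
    for (tp in c("T0", "T1")) {
      f[[tp]] <- t(vapply(f$patches[[tp]], function(p) {
        encoder_forward(p, params, config)$g
      }, numeric(utils::tail(config$encoder_channels, 1))))
    }
    f
  })
}

# Column statistics of the encoder features over a training set (all
# regions and timepoints pooled).  Standardizing with these makes the
# between-patient feature variation unit-scale, which the attention and
# classifier stack trains on.
feat_stats <- function(features) {
  G <- do.call(rbind, lapply(features, function(f) rbind(f$T0, f$T1)))
  mu <- colMeans(G)
  sd <- apply(G, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

apply_feat_stats <- function(features, st) {
  lapply(features, function(f) {
    for (tp in c("T0", "T1")) {
      f[[tp]] <- sweep(sweep(f[[tp]], 2, st$mu), 2, st$sd, "/")
    }
    f
  })
}

scores_from_features <- function(params, feats, config, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(feats)
  vapply(idx, function(i) {
    sti_forward_tokens(params, feats[[i]], config)$score
  }, numeric(1))
}

# Core optimization loop (Adam, minibatches, class-weighted BCE).
train_loop <- function(feats, labels, params, config, epochs, lr,
                       weight_decay, batch_size, train_idx,
                       val_idx = NULL, seed = 1L, verbose = FALSE) {
  n_stage <- length(params$conv)
  unfreeze <- config$training$layerwise_unfreeze
  unfrozen_from <- n_stage + 1L   # no conv stage trainable yet
  head_names <- setdiff(names(params), "conv")
  head_params <- params[head_names]
  opt <- adam_init(head_params)
  opt_conv <- NULL
  y <- as.numeric(labels[train_idx])
  w <- rep(1, length(y))
  if (config$training$class_weighting) {
    w <- ifelse(y == 1, length(y) / (2 * sum(y == 1)),
                length(y) / (2 * sum(y == 0)))
  }
  metric_hist <- numeric(0)
  plateau <- 0L
  history <- list()
  withr_seed(seed, {
    for (ep in seq_len(epochs)) {
      conv_active <- unfreeze && unfrozen_from <= n_stage
      ord <- sample(seq_along(train_idx))
      for (start in seq(1, length(ord), by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
        gacc <- NULL
        gconv <- NULL
        for (b in bidx) {
          i <- train_idx[b]
          f <- feats[[i]]
          enc <- NULL
          if (conv_active) {
            enc <- list()
            for (tp in c("T0", "T1")) {
              enc[[tp]] <- lapply(f$patches[[tp]], encoder_forward,
                                  params = params, config = config,
                                  keep = TRUE)
              f[[tp]] <- t(vapply(enc[[tp]], `[[`, f[[tp]][1, ], "g"))
            }
          }
          drop_mask <- NULL
          if (config$dropout > 0) {
            drop_mask <- (stats::runif(config$embed_dim) >
                            config$dropout) / (1 - config$dropout)
          }
          fwd <- sti_forward_tokens(params, f, config, drop_mask)
          dlogit <- w[b] * (fwd$score - y[b]) / length(bidx)
          bw <- sti_backward_tokens(dlogit, fwd, params, f, config)
          gacc <- if (is.null(gacc)) bw$grads else tree_add(gacc, bw$grads)
          if (conv_active) {
            for (tp in active_timepoints(config)) {
              for (r in seq_len(nrow(bw$dG[[tp]]))) {
                dg <- bw$dG[[tp]][r, ]
                if (all(dg == 0)) next
                cg <- encoder_backward(enc[[tp]][[r]], dg, params, config,
                                       down_to = unfrozen_from)
                gconv <- if (is.null(gconv)) cg else tree_add(gconv, cg)
              }
            }
          }
        }
        st <- adam_step(head_params, gacc, opt, lr, weight_decay)
        head_params <- st$params
        opt <- st$state
        params[head_names] <- head_params
        if (conv_active && !is.null(gconv)) {
          if (is.null(opt_conv)) opt_conv <- adam_init(params$conv)
          stc <- adam_step(params$conv, gconv, opt_conv, lr * 0.1,
                           weight_decay)
          params$conv <- stc$params
          opt_conv <- stc$state
        }
      }
      if (conv_active) feats <- refresh_features(feats, params, config)
      # plateau-driven layerwise unfreezing on the monitored AUC
      monitor_idx <- if (!is.null(val_idx) && length(val_idx)) val_idx
                     else train_idx
      if (unfreeze || verbose) {
        sc <- scores_from_features(params, feats, config, monitor_idx)
        m <- if (length(unique(labels[monitor_idx])) > 1L) {
          roc_auc(sc, labels[monitor_idx])
        } else NA_real_
        metric_hist <- c(metric_hist, m)
        if (unfreeze && length(metric_hist) > 1L && !is.na(m)) {
          if (m < max(metric_hist[-length(metric_hist)], na.rm = TRUE) +
                0.005) {
            plateau <- plateau + 1L
          } else {
            plateau <- 0L
          }
          if (plateau >= 3L && unfrozen_from > 1L) {
            unfrozen_from <- unfrozen_from - 1L
            plateau <- 0L
            if (verbose) {
              message(sprintf("epoch %d: unfreezing conv stage %d", ep,
                              unfrozen_from))
            }
          }
        }
        history[[ep]] <- list(epoch = ep, metric = m,
                              unfrozen_from = unfrozen_from)
      }
    }
  })
  list(params = params, feats = feats, history = history)
}

stratified_folds <- function(labels, k, seed) {
  withr_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit the spatiotemporal interaction model
#'
#' End-to-end fitting on a labelled cohort: kinetic habitat segmentation and
#' region-patch preprocessing per case, Siamese encoding of every region at
#' both timepoints, then training of the attention/classifier stack by
#' class-weighted binary cross-entropy with Adam.  Hyperparameter
#' combinations listed in `config$training$grid` are scored by stratified
#' k-fold cross-validated AUC; the best combination is refit on the full
#' cohort.  The classification threshold is chosen by the Youden index on
#' the training scores.
#'
#' @param cohort An `sti_cohort` (or list of `longitudinal_case`s) with pCR
#'   labels and at least two cases per class.
#' @param config An [sti_config()].
#' @param variant Optional name from [sti_variants()]; overrides the
#'   ablation flags in `config`.
#' @param preproc A [preproc_config()].
#' @param features Precomputed [extract_features()] result (advanced; lets
#'   several variants share one encoding pass).
#' @param cv Run the cross-validation stage (default: yes whenever
#'   `config$training$folds >= 2`).  With `cv = FALSE` the first grid
#'   combination is used directly.
#' @param verbose Print progress.
#' @return Object of class `sti_model`.
#' @export
sti_fit <- function(cohort, config = sti_config(), variant = NULL,
                    preproc = preproc_config(), features = NULL,
                    cv = config$training$folds >= 2, verbose = FALSE) {
  if (!is.null(variant)) config <- sti_variant_config(variant, config)
  validate_sti_config(config)
  labels <- cohort_labels(cohort)
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop("need at least 2 cases per class")
  }
  params <- sti_init_params(config)
  if (is.null(features)) {
    features <- extract_features(cohort, params, config, preproc,
                                 keep_patches = config$training$layerwise_unfreeze)
  }
  tr <- config$training
  grid <- tr$grid
  combos <- if (length(grid)) {
    expand.grid(grid, stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = "1")
  }
  combo_training <- function(row) {
    t2 <- tr
    if (ncol(combos)) {
      for (nm in names(combos)) t2[[nm]] <- combos[row, nm]
    }
    t2
  }
  cv_results <- NULL
  best_row <- 1L
  if (cv && tr$folds >= 2L) {
    fold <- stratified_folds(labels, tr$folds, config$seed)
    cv_auc <- matrix(NA_real_, nrow(combos), tr$folds)
    for (r in seq_len(nrow(combos))) {
      t2 <- combo_training(r)
      for (f in seq_len(tr$folds)) {
        tr_idx <- which(fold != f)
        va_idx <- which(fold == f)
        nfeats <- apply_feat_stats(features, feat_stats(features[tr_idx]))
        res <- train_loop(nfeats, labels, sti_init_params(config), config,
                          epochs = t2$epochs, lr = t2$learning_rate,
                          weight_decay = t2$weight_decay,
                          batch_size = t2$batch_size,
                          train_idx = tr_idx, val_idx = va_idx,
                          seed = config$seed + 131L * f + r)
        sc <- scores_from_features(res$params, res$feats, config, va_idx)
        cv_auc[r, f] <- if (length(unique(labels[va_idx])) > 1L) {
          roc_auc(sc, labels[va_idx])
        } else NA_real_
      }
      if (verbose) {
        message(sprintf("grid combo %d/%d: mean CV AUC %.3f", r,
                        nrow(combos), mean(cv_auc[r, ], na.rm = TRUE)))
      }
    }
    mean_auc <- rowMeans(cv_auc, na.rm = TRUE)
    best_row <- which.max(mean_auc)
    cv_results <- list(fold_auc = cv_auc, mean_auc = mean_auc,
                       grid = combos, best = best_row)
  }
  t2 <- combo_training(best_row)
  stats <- feat_stats(features)
  features <- apply_feat_stats(features, stats)
  res <- train_loop(features, labels, params, config,
                    epochs = t2$epochs, lr = t2$learning_rate,
                    weight_decay = t2$weight_decay,
                    batch_size = t2$batch_size,
                    train_idx = seq_along(labels), seed = config$seed,
                    verbose = verbose)
  train_scores <- scores_from_features(res$params, res$feats, config)
  threshold <- youden_threshold(train_scores, labels)
  structure(list(params = res$params, config = config, preproc = preproc,
                 feat_stats = stats,
                 variant = if (is.null(variant)) "custom" else variant,
                 threshold = threshold, cv = cv_results,
                 best_training = t2,
                 train_scores = train_scores, train_labels = labels,
                 history = res$history),
            class = "sti_model")
}

#' @export
print.sti_model <- function(x, ...) {
  a <- x$config$ablation
  cat(sprintf("STI model (variant: %s)\n", x$variant))
  cat(sprintf("  timepoints: %s | regions: %s | spatial att: %s | temporal att: %s\n",
              paste(active_timepoints(x$config), collapse = "+"),
              paste(c(if (a$use_whole_tumor) "whole",
                      if (a$use_subregions) sprintf("%d habitats",
                                                    x$config$K)),
                    collapse = " + "),
              a$use_spatial_attention, a$use_temporal_attention))
  cat(sprintf("  embed_dim %d, heads %d/%d, threshold %.3f\n",
              x$config$embed_dim, x$config$n_heads_spatial,
              x$config$n_heads_temporal, x$threshold))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV mean AUC (best combo): %.3f\n",
                x$cv$mean_auc[x$cv$best]))
  }
  cat(sprintf("  training AUC: %.3f (n = %d, %.0f%% pCR)\n",
              roc_auc(x$train_scores, x$train_labels),
              length(x$train_labels), 100 * mean(x$train_labels)))
  invisible(x)
}

#' @export
summary.sti_model <- function(object, ...) {
  rep <- score_metrics(object$train_scores, object$train_labels,
                       threshold = object$threshold, ap_reps = 200)
  cat("Training-set performance (resubstitution; use held-out data for\n")
  cat("honest estimates):\n")
  print(rep)
  invisible(rep)
}

#' @export
plot.sti_model <- function(x, ...) {
  o <- order(x$train_scores, decreasing = TRUE)
  y <- x$train_labels[o]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(!y) / sum(!y))
  graphics::plot(fpr, tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("Training ROC (AUC %.3f)",
                                roc_auc(x$train_scores, x$train_labels)),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Predict response scores for a cohort
#'
#' @param object A fitted [sti_fit()] model.
#' @param cohort Cohort of `longitudinal_case`s.
#' @param type `"df"` (default): data frame with `patient_id`, `score`,
#'   `label_pred`, `threshold`; `"response"`: numeric scores;
#'   `"embedding"`: matrix of fused pre-classifier embeddings (the model's
#'   deep features).
#' @param features Optional precomputed [extract_features()].
#' @param ... Unused.
#' @export
predict.sti_model <- function(object, cohort, type = c("df", "response",
                                                       "embedding"),
                              features = NULL, ...) {
  type <- match.arg(type)
  if (is.null(features)) {
    features <- extract_features(cohort, object$params, object$config,
                                 object$preproc)
  }
  if (!is.null(object$feat_stats)) {
    features <- apply_feat_stats(features, object$feat_stats)
  }
  fwd <- lapply(features, function(f) {
    sti_forward_tokens(object$params, f, object$config)
  })
  if (type == "embedding") {
    emb <- t(vapply(fwd, `[[`, numeric(object$config$embed_dim), "fused"))
    rownames(emb) <- vapply(cohort, `[[`, character(1), "patient_id")
    return(emb)
  }
  scores <- vapply(fwd, `[[`, numeric(1), "score")
  if (type == "response") return(scores)
  data.frame(patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
             score = scores,
             label_pred = scores >= object$threshold,
             threshold = object$threshold,
             stringsAsFactors = FALSE)
}

#' Forward pass for a single case
#'
#' Composes crop, Siamese encoding, spatial and temporal attention and the
#' classification head for one longitudinal case, honouring every ablation
#' flag of the model's config.
#'
#' @param case A `longitudinal_case`.
#' @param model A fitted (or freshly initialized) `sti_model`.
#' @return One-row prediction data frame (`patient_id`, `score`,
#'   `label_pred`, `threshold`).
#' @export
forward_sti <- function(case, model) {
  predict(model, list(case))
}

#' Untrained model at its seeded initialization
#'
#' Useful for initialization contracts and as a warm-start hook: returns an
#' `sti_model` whose parameters are the seeded random initialization (with
#' zero final classifier layer, so every score is exactly 0.5).
#'
#' @param config An [sti_config()].
#' @param preproc A [preproc_config()].
#' @return An `sti_model` with empty training history.
#' @export
sti_untrained <- function(config = sti_config(),
                          preproc = preproc_config()) {
  structure(list(params = sti_init_params(config), config = config,
                 preproc = preproc, variant = "untrained", threshold = 0.5,
                 cv = NULL, train_scores = numeric(0),
                 train_labels = logical(0), history = list()),
            class = "sti_model")
}

#' Grad-CAM heatmaps for one case
#'
#' Gradient-weighted class activation maps at the last conv stage of the
#' shared encoder: channel weights are the gradient of the logit with
#' respect to the global-average-pooled features, the weighted activation
#' sum is ReLU-rectified, trilinearly upsampled to the patch grid and
#' min-max normalized to \[0, 1\].  One heatmap per enabled region and
#' timepoint.
#'
#' @param model A fitted `sti_model`.
#' @param case A `longitudinal_case`.
#' @return Nested list `heatmaps[[timepoint]][[region]]` of arrays in
#'   \[0, 1\] of `patch_shape`, each carrying the matching region patch as
#'   attribute `"patch"`.
#' @export
grad_cam <- function(model, case) {
  config <- model$config
  params <- model$params
  habs <- segment_case_habitats(case, K = config$K, seed = config$seed)
  patches <- suppressWarnings(preprocess_case(case, habs, model$preproc))
  feats <- list()
  enc <- list()
  for (tp in c("T0", "T1")) {
    enc[[tp]] <- lapply(patches[[tp]], encoder_forward, params = params,
                        config = config, keep = TRUE)
    feats[[tp]] <- t(vapply(enc[[tp]], `[[`,
                            numeric(utils::tail(config$encoder_channels, 1)),
                            "g"))
  }
  sd_scale <- rep(1, ncol(feats$T0))
  if (!is.null(model$feat_stats)) {
    feats <- apply_feat_stats(list(feats), model$feat_stats)[[1]]
    sd_scale <- model$feat_stats$sd
  }
  fwd <- sti_forward_tokens(params, feats, config)
  bw <- sti_backward_tokens(1, fwd, params, feats, config)
  out <- list()
  region_names <- c("whole", paste0("habitat_", seq_len(config$K)))
  for (tp in active_timepoints(config)) {
    out[[tp]] <- list()
    for (r in active_regions(config)) {
      alpha <- bw$dG[[tp]][r, ] / sd_scale
      A <- enc[[tp]][[r]]$acts_last
      cam <- array(0, dim = dim(A)[1:3])
      for (cc in seq_along(alpha)) {
        cam <- cam + alpha[cc] * A[, , , cc]
      }
      cam[cam < 0] <- 0
      cam <- resize_to_shape(cam, config$patch_shape)
      cam[cam < 0] <- 0
      energy <- mean(cam)          # pre-normalization heat, comparable
      mx <- max(cam)               # across regions
      if (mx > 0) cam <- cam / mx
      attr(cam, "patch") <- patches[[tp]][[region_names[r]]]
      attr(cam, "energy") <- energy
      out[[tp]][[region_names[r]]] <- cam
    }
  }
  # region attribution: mean absolute score gradient at each region token's
  # encoder features (how strongly the decision leans on that region)
  w <- lapply(active_timepoints(config), function(tp) {
    rowMeans(abs(bw$dG[[tp]]))[active_regions(config)]
  })
  names(w) <- active_timepoints(config)
  attr(out, "region_weights") <- w
  attr(out, "score") <- fwd$score
  out
}
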