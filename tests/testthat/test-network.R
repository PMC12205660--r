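test_that("config invariants are enforced", {
  expect_error(sti_config(ablation = list(use_T0 = FALSE, use_T1 = FALSE)),
               "use_T0")
  expect_error(sti_config(ablation = list(use_subregions = FALSE,
                                          use_whole_tumor = FALSE)),
               "use_subregions")
  expect_error(sti_config(embed_dim = 30, n_heads_spatial = 4), "divide")
  expect_error(sti_config(patch_shape = c(20, 20, 20)), "divisible")
  expect_length(sti_variants(), 9)
  for (v in sti_variants()) {
    expect_s3_class(sti_variant_config(v, tiny_sti_config()), "sti_config")
  }
})

test_that("an untrained model scores exactly 0.5 and encodes deterministically", {
  cfg <- tiny_sti_config(seed = 3)
  model <- sti_untrained(cfg, preproc_config(patch_shape = cfg$patch_shape))
  co <- generate_cohort(tiny_phantom(2, seed = 3))
  pr <- predict(model, co)
  expect_equal(pr$score, c(0.5, 0.5))
  expect_equal(forward_sti(co[[1]], model)$score, 0.5)
  # Siamese contract: one parameter set serves every region and timepoint,
  # so identical patches map to identical embeddings
  patch <- list(volume = array(rnorm(16^3), c(16, 16, 16)),
                mask = array(1, c(16, 16, 16)))
  e1 <- encode_region(patch, model$params, cfg)
  e2 <- encode_region(patch, model$params, cfg)
  expect_identical(e1, e2)
  zero <- list(volume = array(0, c(16, 16, 16)),
               mask = array(0, c(16, 16, 16)))
  ez <- encode_region(zero, model$params, cfg)
  expect_true(all(is.finite(ez)))
  patch2 <- list(volume = array(rnorm(16^3), c(16, 16, 16)),
                 mask = array(1, c(16, 16, 16)))
  e3 <- encode_region(patch2, model$params, cfg)
  cossim <- sum(e1 * e3) / sqrt(sum(e1^2) * sum(e3^2))
  expect_lt(cossim, 1 - 1e-6)
  expect_error(encode_region(list(volume = array(0, c(8, 8, 8)),
                                  mask = array(0, c(8, 8, 8))),
                             model$params, cfg), "shape")
})

test_that("backpropagation matches finite differences in both fusion orders", {
  for (order in c("temporal_first", "spatial_first")) {
    cfg <- sti_config(K = 3, patch_shape = c(8, 8, 8), embed_dim = 12,
                      encoder_channels = c(4, 6), n_heads_spatial = 2,
                      n_heads_temporal = 2, dropout = 0, seed = 5,
                      fusion_order = order)
    params <- stimr:::sti_init_params(cfg)
    set.seed(1)
    params$head$W2 <- matrix(rnorm(nrow(params$head$W2), 0, 0.3), ncol = 1)
    feats <- list(T0 = matrix(rnorm(24), 4, 6), T1 = matrix(rnorm(24), 4, 6))
    fwd <- stimr:::sti_forward_tokens(params, feats, cfg)
    bw <- stimr:::sti_backward_tokens(1, fwd, params, feats, cfg)
    eps <- 1e-6
    for (leaf in list(c("temp", "Wv"), c("spat", "Wq"), c("cat", "W"),
                      c("proj", "W"), c("head", "W1"))) {
      W <- params[[leaf[1]]][[leaf[2]]]
      set.seed(2)
      for (i in sample(length(W), 4)) {
        Wp <- W; Wp[i] <- Wp[i] + eps
        params[[leaf[1]]][[leaf[2]]] <- Wp
        lp <- stimr:::sti_forward_tokens(params, feats, cfg)$logit
        Wm <- W; Wm[i] <- Wm[i] - eps
        params[[leaf[1]]][[leaf[2]]] <- Wm
        lm <- stimr:::sti_forward_tokens(params, feats, cfg)$logit
        params[[leaf[1]]][[leaf[2]]] <- W
        expect_equal(bw$grads[[leaf[1]]][[leaf[2]]][i], (lp - lm) / (2 * eps),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("attention blocks honour their algebraic contracts", {
  cfg <- sti_config(K = 3, patch_shape = c(8, 8, 8), embed_dim = 12,
                    encoder_channels = c(4, 6), n_heads_spatial = 2,
                    n_heads_temporal = 2, dropout = 0, seed = 5)
  params <- stimr:::sti_init_params(cfg)
  set.seed(4)
  tokens <- matrix(rnorm(48), 4, 12)
  # spatial attention off: pooled output is the exact arithmetic mean
  cfg_off <- cfg
  cfg_off$ablation$use_spatial_attention <- FALSE
  sa <- spatial_attention(tokens, params, cfg_off)
  expect_equal(sa$pooled, colMeans(tokens), tolerance = 1e-12)
  # single token, attention off: the token itself
  sa1 <- spatial_attention(tokens[1, , drop = FALSE], params, cfg_off)
  expect_equal(sa1$pooled, tokens[1, ], tolerance = 1e-12)
  expect_error(spatial_attention(tokens[0, , drop = FALSE], params, cfg),
               "empty")
  # permuting token order leaves the pooled output unchanged
  sa_a <- spatial_attention(tokens, params, cfg)
  sa_b <- spatial_attention(tokens[c(3, 1, 4, 2), ], params, cfg)
  expect_equal(sa_a$pooled, sa_b$pooled, tolerance = 1e-10)
  # softmax rows of every attention map sum to 1
  for (A in sa_a$cache$mha$A) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
  }
  # temporal symmetry: identical embeddings give identical directional outputs
  e <- rnorm(12)
  ta <- temporal_attention(e, e, params, cfg)
  expect_equal(ta$cache$cc[1, 1:12], ta$cache$cc[1, 13:24], tolerance = 1e-10)
  for (A in c(ta$cache$a0$A, ta$cache$a1$A)) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
  }
  expect_error(temporal_attention(NULL, e, params, cfg), "both")
  # fusion with temporal attention off and subtract: linear in (e1 - e0)
  cfg_sub <- cfg
  cfg_sub$ablation$use_temporal_attention <- FALSE
  cfg_sub$fusion_when_no_temporal_attention <- "subtract"
  e0 <- rnorm(12); e1 <- rnorm(12)
  t1 <- temporal_attention(e0, e1, params, cfg_sub)
  t2 <- temporal_attention(2 * e0, 2 * e1, params, cfg_sub)
  expect_equal(t2$cache$d, 2 * t1$cache$d, tolerance = 1e-12)
  expect_equal(t2$fused - as.numeric(params$fuse_sub$b),
               2 * (t1$fused - as.numeric(params$fuse_sub$b)),
               tolerance = 1e-10)
})

test_that("ablation flags disconnect the unused timepoint", {
  cfg <- sti_variant_config("t0", tiny_sti_config(seed = 2))
  params <- stimr:::sti_init_params(cfg)
  set.seed(6)
  params$head$W2 <- matrix(rnorm(nrow(params$head$W2), 0, 0.3), ncol = 1)
  feats <- list(T0 = matrix(rnorm(4 * 6), 4, 6),
                T1 = matrix(rnorm(4 * 6), 4, 6))
  s1 <- stimr:::sti_forward_tokens(params, feats, cfg)$score
  feats$T1 <- matrix(rnorm(4 * 6, sd = 50), 4, 6)
  s2 <- stimr:::sti_forward_tokens(params, feats, cfg)$score
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 <= 1)
})

test_that("training learns a planted signal and respects epochs = 0", {
  co <- generate_cohort(tiny_phantom(40, seed = 17))
  cfg <- tiny_sti_config(seed = 17, training = list(epochs = 25, folds = 2))
  pre <- preproc_config(patch_shape = cfg$patch_shape)
  m0 <- sti_fit(co, cfg, variant = "sti", preproc = pre, cv = FALSE)
  expect_s3_class(m0, "sti_model")
  expect_gt(roc_auc(m0$train_scores, m0$train_labels), 0.7)
  pr <- predict(m0, co[1:4])
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_equal(pr$label_pred, pr$score >= m0$threshold)
  emb <- predict(m0, co[1:3], type = "embedding")
  expect_equal(dim(emb), c(3L, cfg$embed_dim))
  # epochs = 0 leaves the zero-initialized classifier untouched
  cfg0 <- tiny_sti_config(seed = 17, training = list(epochs = 0))
  mz <- sti_fit(co, cfg0, variant = "sti", preproc = pre, cv = FALSE)
  expect_true(all(mz$train_scores == 0.5))
  expect_error(sti_fit(co[which(cohort_labels(co))[1:3]], cfg,
                       variant = "sti", preproc = pre), "per class")
})

test_that("cross-validated grid search prefers a learning rate that learns", {
  co <- generate_cohort(tiny_phantom(36, seed = 23))
  cfg <- tiny_sti_config(seed = 23,
                         training = list(epochs = 15, folds = 3,
                                         grid = list(learning_rate = c(0, 0.01))))
  pre <- preproc_config(patch_shape = cfg$patch_shape)
  m <- sti_fit(co, cfg, variant = "t0t1", preproc = pre)
  expect_equal(m$best_training$learning_rate, 0.01)
  expect_equal(dim(m$cv$fold_auc), c(2L, 3L))
  # duplicating every case leaves the selected hyperparameters unchanged
  m2 <- sti_fit(c(co, co), cfg, variant = "t0t1", preproc = pre)
  expect_equal(m2$best_training$learning_rate, 0.01)
})

test_that("layerwise unfreezing fine-tunes conv stages when triggered", {
  co <- generate_cohort(tiny_phantom(16, seed = 29))
  cfg <- tiny_sti_config(seed = 29,
                         training = list(epochs = 10,
                                         layerwise_unfreeze = TRUE))
  pre <- preproc_config(patch_shape = cfg$patch_shape)
  m <- sti_fit(co, cfg, variant = "sti", preproc = pre, cv = FALSE)
  hist <- vapply(m$history, function(h) h$unfrozen_from, numeric(1))
  expect_true(all(diff(hist) <= 0))   # stages only ever unfreeze
  if (min(hist) <= length(cfg$encoder_channels)) {
    init <- stimr:::sti_init_params(cfg)
    s <- min(hist)
    expect_false(identical(m$params$conv[[s]]$W, init$conv[[s]]$W))
  }
})

test_that("grad_cam emits normalized per-region heatmaps", {
  co <- generate_cohort(tiny_phantom(24, seed = 37))
  cfg <- tiny_sti_config(seed = 37, training = list(epochs = 15))
  pre <- preproc_config(patch_shape = cfg$patch_shape)
  m <- sti_fit(co, cfg, variant = "sti", preproc = pre, cv = FALSE)
  cams <- grad_cam(m, co[[1]])
  expect_named(cams, c("T0", "T1"))
  for (tp in c("T0", "T1")) {
    expect_named(cams[[tp]], c("whole", "habitat_1", "habitat_2",
                               "habitat_3"))
    for (cam in cams[[tp]]) {
      expect_true(all(cam >= 0 & cam <= 1))
      expect_equal(dim(cam), cfg$patch_shape)
      if (max(cam) > 0) expect_equal(max(cam), 1)
    }
  }
  # all-zero activations give an all-zero map: feed a zero patch through
  # the encoder directly
  zero <- list(volume = array(0, c(16, 16, 16)),
               mask = array(0, c(16, 16, 16)))
  ef <- stimr:::encoder_forward(zero, m$params, cfg, keep = TRUE)
  expect_true(all(ef$acts_last == 0))
})
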