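#' Configuration of the spatiotemporal interaction network
#'
#' Architecture, ablation and training switches.  The ablation flags
#' reproduce every model variant of the comparison grid (single-timepoint,
#' with/without subregions, with/without spatial or temporal attention);
#' see [sti_variant_config()] for the named presets.
#'
#' @param K Habitat count (subregion tokens per timepoint).
#' @param patch_shape Input patch grid; each dimension must be divisible by
#'   `2^length(encoder_channels)` for the pooling stages.
#' @param embed_dim Region-token embedding length.
#' @param encoder_channels Convolution widths of the shared encoder stages.
#' @param n_heads_spatial,n_heads_temporal Attention head counts; must
#'   divide `embed_dim`.
#' @param dropout Dropout probability on the fused embedding during
#'   training (0 disables).
#' @param ablation Named list of logical flags: `use_T0`, `use_T1`,
#'   `use_subregions`, `use_whole_tumor`, `use_spatial_attention`,
#'   `use_temporal_attention`.
#' @param fusion_when_no_temporal_attention `"concatenate"` (default) or
#'   `"subtract"`: how the two timepoint embeddings fuse when temporal
#'   attention is ablated.
#' @param fusion_order `"temporal_first"` (default): each region's T0/T1
#'   tokens are fused across time first and spatial attention runs over
#'   the fused region tokens, so the model forms per-habitat change
#'   features; `"spatial_first"`: region tokens are pooled per timepoint
#'   before temporal fusion.
#' @param seed Seed controlling weight init, fold assignment and data order.
#' @param training Named list: `epochs`, `batch_size`, `learning_rate`,
#'   `weight_decay`, `class_weighting`, `folds`, `grid` (named list of
#'   hyperparameter vectors searched by CV), `layerwise_unfreeze`.
#' @return Object of class `sti_config`.
#' @export
sti_config <- function(K = 3L,
                       patch_shape = c(32L, 32L, 32L),
                       embed_dim = 32L,
                       encoder_channels = c(8L, 16L, 32L),
                       n_heads_spatial = 4L,
                       n_heads_temporal = 4L,
                       dropout = 0.2,
                       ablation = list(),
                       fusion_when_no_temporal_attention = c("concatenate",
                                                             "subtract"),
                       fusion_order = c("temporal_first", "spatial_first"),
                       seed = 1L,
                       training = list()) {
  abl <- utils::modifyList(list(use_T0 = TRUE, use_T1 = TRUE,
                                use_subregions = TRUE,
                                use_whole_tumor = TRUE,
                                use_spatial_attention = TRUE,
                                use_temporal_attention = TRUE),
                           ablation)
  tr <- utils::modifyList(list(epochs = 50L, batch_size = 32L,
                               learning_rate = 0.01, weight_decay = 5e-4,
                               class_weighting = TRUE, folds = 5L,
                               grid = list(), layerwise_unfreeze = FALSE),
                          training)
  cfg <- structure(list(
    K = as.integer(K),
    patch_shape = as.integer(patch_shape),
    embed_dim = as.integer(embed_dim),
    encoder_channels = as.integer(encoder_channels),
    n_heads_spatial = as.integer(n_heads_spatial),
    n_heads_temporal = as.integer(n_heads_temporal),
    dropout = dropout,
    ablation = abl,
    fusion_when_no_temporal_attention =
      match.arg(fusion_when_no_temporal_attention),
    fusion_order = match.arg(fusion_order),
    seed = as.integer(seed),
    training = tr), class = "sti_config")
  validate_sti_config(cfg)
  cfg
}

validate_sti_config <- function(cfg) {
  a <- cfg$ablation
  if (!a$use_T0 && !a$use_T1) {
    stop("at least one of use_T0/use_T1 must be enabled")
  }
  if (!a$use_subregions && !a$use_whole_tumor) {
    stop("at least one of use_subregions/use_whole_tumor must be enabled")
  }
  if (cfg$embed_dim %% cfg$n_heads_spatial != 0 ||
      cfg$embed_dim %% cfg$n_heads_temporal != 0) {
    stop("head counts must divide embed_dim")
  }
  div <- 2^length(cfg$encoder_channels)
  if (any(cfg$patch_shape %% div != 0)) {
    stop("patch_shape must be divisible by 2^(number of encoder stages)")
  }
  invisible(cfg)
}

#' Named ablation presets of the model-variant grid
#'
#' `sti_variants()` lists the nine configured variants: the six
#' time/space comparison models (`t0`, `t1`, `t0_spatial`, `t1_spatial`,
#' `t0t1`, `sti`), the subregion-only model (`only_spatial`) and the two
#' attention ablations (`no_spatial_attention`, `no_time_attention`).
#' `sti_variant_config()` returns a config with the corresponding flags.
#'
#' @param variant Variant name.
#' @param base An `sti_config` whose non-ablation settings are kept.
#' @return `sti_variants()`: character vector; `sti_variant_config()`: an
#'   `sti_config`.
#' @export
sti_variants <- function() {
  c("t0", "t1", "t0_spatial", "t1_spatial", "t0t1",
    "only_spatial", "no_spatial_attention", "no_time_attention", "sti")
}

#' @rdname sti_variants
#' @export
sti_variant_config <- function(variant, base = sti_config()) {
  flags <- switch(variant,
    t0 = list(use_T0 = TRUE, use_T1 = FALSE, use_subregions = FALSE,
              use_whole_tumor = TRUE, use_spatial_attention = FALSE,
              use_temporal_attention = FALSE),
    t1 = list(use_T0 = FALSE, use_T1 = TRUE, use_subregions = FALSE,
              use_whole_tumor = TRUE, use_spatial_attention = FALSE,
              use_temporal_attention = FALSE),
    t0_spatial = list(use_T0 = TRUE, use_T1 = FALSE, use_subregions = TRUE,
                      use_whole_tumor = TRUE, use_spatial_attention = TRUE,
                      use_temporal_attention = FALSE),
    t1_spatial = list(use_T0 = FALSE, use_T1 = TRUE, use_subregions = TRUE,
                      use_whole_tumor = TRUE, use_spatial_attention = TRUE,
                      use_temporal_attention = FALSE),
    t0t1 = list(use_T0 = TRUE, use_T1 = TRUE, use_subregions = FALSE,
                use_whole_tumor = TRUE, use_spatial_attention = FALSE,
                use_temporal_attention = FALSE),
    only_spatial = list(use_T0 = TRUE, use_T1 = TRUE, use_subregions = TRUE,
                        use_whole_tumor = FALSE,
                        use_spatial_attention = TRUE,
                        use_temporal_attention = TRUE),
    no_spatial_attention = list(use_T0 = TRUE, use_T1 = TRUE,
                                use_subregions = TRUE,
                                use_whole_tumor = TRUE,
                                use_spatial_attention = FALSE,
                                use_temporal_attention = TRUE),
    no_time_attention = list(use_T0 = TRUE, use_T1 = TRUE,
                             use_subregions = TRUE, use_whole_tumor = TRUE,
                             use_spatial_attention = TRUE,
                             use_temporal_attention = FALSE),
    sti = list(use_T0 = TRUE, use_T1 = TRUE, use_subregions = TRUE,
               use_whole_tumor = TRUE, use_spatial_attention = TRUE,
               use_temporal_attention = TRUE),
    stop("unknown variant: ", variant)
  )
  base$ablation <- utils::modifyList(base$ablation, flags)
  validate_sti_config(base)
  base
}

# ---- parameter initialization ----------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# Initializes the full parameter tree.  The classifier's final layer is
# zero-initialized so an untrained model scores exactly 0.5.
sti_init_params <- function(config) {
  withr_seed(config$seed, {
    D <- config$embed_dim
    ch <- config$encoder_channels
    # 3 input channels: intensity, region mask, masked intensity
    cin <- c(3L, ch[-length(ch)])
    conv <- lapply(seq_along(ch), function(s) {
      list(W = he_init(c(3, 3, 3, cin[s], ch[s]), 27 * cin[s]),
           b = numeric(ch[s]))
    })
    names(conv) <- paste0("stage", seq_along(ch))
    C <- ch[length(ch)]
    H <- 32L
    att <- function() list(Wq = he_init(c(D, D), D) / sqrt(2),
                           Wk = he_init(c(D, D), D) / sqrt(2),
                           Wv = he_init(c(D, D), D) / sqrt(2),
                           Wo = he_init(c(D, D), D) / sqrt(2) * 0.1)
    list(conv = conv,
         proj = list(W = he_init(c(C, D), C), b = numeric(D)),
         type_region = he_init(c(config$K + 1L, D), D) * 0.3,
         type_time = he_init(c(2L, D), D) * 0.3,
         spat = att(),
         temp = att(),
         cat = list(W = he_init(c(2L * D, D), 2 * D), b = numeric(D)),
         fuse_cat = list(W = he_init(c(2L * D, D), 2 * D), b = numeric(D)),
         fuse_sub = list(W = he_init(c(D, D), D), b = numeric(D)),
         head = list(W1 = he_init(c(D, H), D), b1 = numeric(H),
                     W2 = matrix(0, H, 1), b2 = 0))
  })
}

# ---- shared region encoder --------------------------------------------------

# Forward pass of the shared conv encoder on one region patch.
# Input channels: normalized intensity + region mask.  Returns the
# global-average-pooled feature vector; with keep = TRUE also every
# intermediate needed for backprop / Grad-CAM.
encoder_forward <- function(patch, params, config, keep = FALSE) {
  ps <- config$patch_shape
  x <- array(c(patch$volume, patch$mask, patch$volume * patch$mask),
             dim = c(ps, 3L))
  caches <- if (keep) list() else NULL
  n_stage <- length(params$conv)
  acts_last <- NULL
  for (s in seq_len(n_stage)) {
    pre <- .conv3d_fwd(x, params$conv[[s]]$W, params$conv[[s]]$b)
    act <- pre
    act[act < 0] <- 0
    if (keep) caches[[s]] <- list(x = x, mask_pos = pre > 0)
    if (s == n_stage) acts_last <- act
    x <- .avgpool3d_fwd(act)
  }
  C <- dim(x)[4]
  g <- colMeans(matrix(x, ncol = C))
  out <- list(g = g, pooled_dim = dim(x))
  if (keep) {
    out$caches <- caches
    out$acts_last <- acts_last
  }
  out
}

# Backprop dg (gradient at the GAP features) through the conv stack.
# Returns gradients for the conv parameter tree (zeros for frozen stages
# below `down_to`) plus nothing else; gradient wrt the input is discarded.
encoder_backward <- function(fwd, dg, params, config, down_to = 1L) {
  n_stage <- length(params$conv)
  pd <- fwd$pooled_dim
  n_vox <- prod(pd[1:3])
  dx <- array(rep(dg / n_vox, each = n_vox), dim = pd)
  grads <- lapply(params$conv, function(p) list(W = p$W * 0,
                                                b = p$b * 0))
  for (s in rev(seq_len(n_stage))) {
    dact <- .avgpool3d_bwd(dx, dim(fwd$caches[[s]]$mask_pos))
    dact[!fwd$caches[[s]]$mask_pos] <- 0
    bw <- .conv3d_bwd(fwd$caches[[s]]$x, params$conv[[s]]$W, dact)
    grads[[s]]$W <- bw$gw
    grads[[s]]$b <- bw$gb
    if (s == down_to) break
    dx <- bw$gx
  }
  grads
}

#' Encode a region patch with the shared Siamese encoder
#'
#' Small 3D convolutional backbone (conv-ReLU-pool stages per
#' `encoder_channels`, global average pooling, linear projection to
#' `embed_dim`).  The identical parameters are used for every region and
#' timepoint — the Siamese weight-sharing contract.
#'
#' @param patch A `region_patch` of the configured shape.
#' @param params Parameter tree of a model (e.g. `model$params`).
#' @param config The `sti_config`.
#' @return Numeric embedding vector of length `embed_dim`.
#' @export
encode_region <- function(patch, params, config) {
  if (!all(dim(patch$volume) == config$patch_shape)) {
    stop("patch shape does not match config")
  }
  f <- encoder_forward(patch, params, config)
  as.numeric(f$g %*% params$proj$W + params$proj$b)
}

# ---- token-level forward/backward -------------------------------------------

# Which tokens a config uses: returns integer region-type indices
# (1 = whole tumor, 1 + h = habitat h).
active_regions <- function(config) {
  r <- integer(0)
  if (config$ablation$use_whole_tumor) r <- c(r, 1L)
  if (config$ablation$use_subregions) r <- c(r, 1L + seq_len(config$K))
  r
}

active_timepoints <- function(config) {
  tps <- character(0)
  if (config$ablation$use_T0) tps <- c(tps, "T0")
  if (config$ablation$use_T1) tps <- c(tps, "T1")
  tps
}

#' Spatial attention over region tokens
#'
#' Multi-head self-attention over the set of (whole-tumor + habitat) tokens
#' of one timepoint, with a residual connection, followed by mean pooling
#' to one timepoint embedding.  With spatial attention ablated the pooled
#' output is the plain arithmetic mean of the tokens.
#'
#' @param tokens Matrix (n_tokens x embed_dim) of region embeddings
#'   (type encodings included).
#' @param params Parameter tree.
#' @param config The `sti_config`.
#' @return List with `pooled` (embed_dim vector) and a cache for backprop.
#' @export
spatial_attention <- function(tokens, params, config) {
  if (is.null(dim(tokens))) tokens <- matrix(tokens, nrow = 1)
  if (nrow(tokens) == 0L) stop("empty token set")
  if (!config$ablation$use_spatial_attention) {
    return(list(pooled = colMeans(tokens), cache = NULL))
  }
  # pre-LN block: residual on the raw tokens, attention computed on
  # normalized tokens so the softmax logits stay in range
  ln <- lapply(seq_len(nrow(tokens)), function(i) layer_norm_fwd(tokens[i, ]))
  Xn <- do.call(rbind, lapply(ln, `[[`, "y"))
  att <- mha_forward(Xn, Xn, params$spat, config$n_heads_spatial)
  list(pooled = colMeans(tokens + att$Y),
       cache = list(mha = att$cache, ln = lapply(ln, `[[`, "cache")))
}

#' Temporal attention across the two timepoints
#'
#' Bidirectional multi-head cross-attention with shared weights: each
#' timepoint embedding queries over the pair of timepoint embeddings (its
#' own and the other timepoint's, so the softmax is content-dependent),
#' residual connections, and the two outputs are concatenated and linearly
#' projected back to `embed_dim`.  With temporal attention ablated the
#' embeddings fuse per `fusion_when_no_temporal_attention`.
#'
#' @param e0,e1 Timepoint embeddings (embed_dim vectors).
#' @param params Parameter tree.
#' @param config The `sti_config`.
#' @return List with `fused` (embed_dim vector) and a cache.
#' @export
temporal_attention <- function(e0, e1, params, config) {
  if (is.null(e0) || is.null(e1)) {
    stop("both timepoint embeddings required for a two-timepoint config")
  }
  if (config$ablation$use_temporal_attention) {
    # pre-normalized embeddings keep the softmax and residual scales sane
    ln0 <- layer_norm_fwd(e0)
    ln1 <- layer_norm_fwd(e1)
    En <- rbind(ln0$y, ln1$y)
    a0 <- mha_forward(En[1, , drop = FALSE], En, params$temp,
                      config$n_heads_temporal)
    a1 <- mha_forward(En[2, , drop = FALSE], En, params$temp,
                      config$n_heads_temporal)
    cc <- cbind(matrix(e0, 1) + a0$Y, matrix(e1, 1) + a1$Y)
    fused <- as.numeric(cc %*% params$cat$W + params$cat$b)
    return(list(fused = fused,
                cache = list(mode = "attention", a0 = a0$cache,
                             a1 = a1$cache, cc = cc,
                             ln0 = ln0$cache, ln1 = ln1$cache)))
  }
  if (config$fusion_when_no_temporal_attention == "concatenate") {
    cc <- matrix(c(e0, e1), 1)
    fused <- as.numeric(cc %*% params$fuse_cat$W + params$fuse_cat$b)
    list(fused = fused, cache = list(mode = "concatenate", cc = cc))
  } else {
    d <- matrix(e1 - e0, 1)
    fused <- as.numeric(d %*% params$fuse_sub$W + params$fuse_sub$b)
    list(fused = fused, cache = list(mode = "subtract", d = d))
  }
}

# Forward from cached GAP features to the score.
# feats: list with per-timepoint matrices of GAP features, one row per
# region in fixed order (whole, habitat_1, ..., habitat_K); the rows the
# ablation enables are selected here.  With fusion_order "temporal_first"
# each region's T0/T1 tokens are fused by temporal attention first and
# spatial attention runs over the fused region tokens; with
# "spatial_first" the region tokens are pooled per timepoint first and
# temporal attention fuses the two timepoint embeddings.
sti_forward_tokens <- function(params, feats, config, drop_mask = NULL) {
  regions <- active_regions(config)
  tps <- active_timepoints(config)
  D <- config$embed_dim
  build_tokens <- function(tp) {
    G <- feats[[tp]][regions, , drop = FALSE]
    G %*% params$proj$W +
      matrix(params$proj$b, nrow(G), D, byrow = TRUE) +
      params$type_region[regions, , drop = FALSE] +
      matrix(params$type_time[if (tp == "T0") 1L else 2L, ],
             nrow(G), D, byrow = TRUE)
  }
  cache <- list(X = list(), spat = list(), temp = NULL, order = NULL)
  for (tp in tps) cache$X[[tp]] <- build_tokens(tp)
  # without temporal attention there is no token-level temporal
  # interaction: the model reverts to late fusion (per-timepoint spatial
  # pooling, then concatenate/subtract), whatever the configured order
  effective_order <- if (config$fusion_order == "temporal_first" &&
                           config$ablation$use_temporal_attention) {
    "temporal_first"
  } else {
    "spatial_first"
  }
  if (length(tps) == 1L) {
    sa <- spatial_attention(cache$X[[tps]], params, config)
    cache$spat[[tps]] <- sa$cache
    fused <- sa$pooled
    cache$order <- "single"
  } else if (effective_order == "temporal_first") {
    tf <- temporal_first_fwd(cache$X$T0, cache$X$T1, params, config)
    sa <- spatial_attention(tf$Ftok, params, config)
    cache$temp <- tf$cache
    cache$Ftok <- tf$Ftok
    cache$spat[["fused"]] <- sa$cache
    fused <- sa$pooled
    cache$order <- "temporal_first"
  } else {
    e <- list()
    for (tp in tps) {
      sa <- spatial_attention(cache$X[[tp]], params, config)
      cache$spat[[tp]] <- sa$cache
      e[[tp]] <- sa$pooled
    }
    ta <- temporal_attention(e$T0, e$T1, params, config)
    fused <- ta$fused
    cache$temp <- ta$cache
    cache$e <- e
    cache$order <- "spatial_first"
  }
  if (!is.null(drop_mask)) fused <- fused * drop_mask
  fln <- layer_norm_fwd(fused)
  hpre <- as.numeric(fln$y %*% params$head$W1 + params$head$b1)
  h <- pmax(hpre, 0)
  logit <- sum(h * params$head$W2) + params$head$b2
  cache$fused <- fused
  cache$fln <- fln
  cache$hpre <- hpre
  cache$h <- h
  cache$drop_mask <- drop_mask
  list(score = stats::plogis(logit), logit = logit, fused = fused,
       cache = cache)
}

# Rowwise layer norm of a token matrix (no learned affine).
ln_rows_fwd <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowMeans(Xc^2) + eps)
  list(y = Xc / s, s = s)
}

ln_rows_bwd <- function(dY, cache) {
  y <- cache$y
  (dY - rowMeans(dY) - y * rowMeans(dY * y)) / cache$s
}

# Batched bidirectional temporal attention over all region pairs at once:
# for every region, its T0/T1 tokens query over the normalized pair and the
# residual outputs are concatenated and projected to one fused region
# token.  Identical math to temporal_attention() applied per region.
temporal_first_fwd <- function(X0, X1, params, config) {
  D <- config$embed_dim
  n <- nrow(X0)
  if (!config$ablation$use_temporal_attention) {
    if (config$fusion_when_no_temporal_attention == "concatenate") {
      cc <- cbind(X0, X1)
      Ftok <- cc %*% params$fuse_cat$W +
        matrix(params$fuse_cat$b, n, D, byrow = TRUE)
      return(list(Ftok = Ftok, cache = list(mode = "concatenate", cc = cc)))
    }
    dd <- X1 - X0
    Ftok <- dd %*% params$fuse_sub$W +
      matrix(params$fuse_sub$b, n, D, byrow = TRUE)
    return(list(Ftok = Ftok, cache = list(mode = "subtract", d = dd)))
  }
  H <- config$n_heads_temporal
  dk <- D / H
  ln0 <- ln_rows_fwd(X0)
  ln1 <- ln_rows_fwd(X1)
  W <- params$temp
  Q0 <- ln0$y %*% W$Wq; Q1 <- ln1$y %*% W$Wq
  K0 <- ln0$y %*% W$Wk; K1 <- ln1$y %*% W$Wk
  V0 <- ln0$y %*% W$Wv; V1 <- ln1$y %*% W$Wv
  O0 <- matrix(0, n, D); O1 <- matrix(0, n, D)
  A0 <- vector("list", H); A1 <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    sm2 <- function(s1, s2) {
      m <- pmax(s1, s2)
      e1 <- exp(s1 - m); e2 <- exp(s2 - m)
      cbind(e1, e2) / (e1 + e2)
    }
    a <- sm2(rowSums(Q0[, idx, drop = FALSE] * K0[, idx, drop = FALSE]) / sqrt(dk),
             rowSums(Q0[, idx, drop = FALSE] * K1[, idx, drop = FALSE]) / sqrt(dk))
    b <- sm2(rowSums(Q1[, idx, drop = FALSE] * K0[, idx, drop = FALSE]) / sqrt(dk),
             rowSums(Q1[, idx, drop = FALSE] * K1[, idx, drop = FALSE]) / sqrt(dk))
    O0[, idx] <- a[, 1] * V0[, idx, drop = FALSE] + a[, 2] * V1[, idx, drop = FALSE]
    O1[, idx] <- b[, 1] * V0[, idx, drop = FALSE] + b[, 2] * V1[, idx, drop = FALSE]
    A0[[h]] <- a; A1[[h]] <- b
  }
  Y0 <- X0 + O0 %*% W$Wo
  Y1 <- X1 + O1 %*% W$Wo
  cc <- cbind(Y0, Y1)
  Ftok <- cc %*% params$cat$W + matrix(params$cat$b, n, D, byrow = TRUE)
  list(Ftok = Ftok,
       cache = list(mode = "attention", ln0 = ln0, ln1 = ln1, Q0 = Q0,
                    Q1 = Q1, K0 = K0, K1 = K1, V0 = V0, V1 = V1, A0 = A0,
                    A1 = A1, O0 = O0, O1 = O1, cc = cc, H = H, dk = dk))
}

temporal_first_bwd <- function(dFtok, tc, params, config, g) {
  D <- config$embed_dim
  n <- nrow(dFtok)
  if (tc$mode == "concatenate") {
    g$fuse_cat$W <- g$fuse_cat$W + t(tc$cc) %*% dFtok
    g$fuse_cat$b <- g$fuse_cat$b + colSums(dFtok)
    dcc <- dFtok %*% t(params$fuse_cat$W)
    return(list(dX0 = dcc[, 1:D, drop = FALSE],
                dX1 = dcc[, D + 1:D, drop = FALSE], g = g))
  }
  if (tc$mode == "subtract") {
    g$fuse_sub$W <- g$fuse_sub$W + t(tc$d) %*% dFtok
    g$fuse_sub$b <- g$fuse_sub$b + colSums(dFtok)
    dd <- dFtok %*% t(params$fuse_sub$W)
    return(list(dX0 = -dd, dX1 = dd, g = g))
  }
  W <- params$temp
  H <- tc$H
  dk <- tc$dk
  g$cat$W <- g$cat$W + t(tc$cc) %*% dFtok
  g$cat$b <- g$cat$b + colSums(dFtok)
  dcc <- dFtok %*% t(params$cat$W)
  dY0 <- dcc[, 1:D, drop = FALSE]
  dY1 <- dcc[, D + 1:D, drop = FALSE]
  dX0 <- dY0
  dX1 <- dY1
  dO0 <- dY0 %*% t(W$Wo)
  dO1 <- dY1 %*% t(W$Wo)
  g$temp$Wo <- g$temp$Wo + t(tc$O0) %*% dY0 + t(tc$O1) %*% dY1
  dQ0 <- matrix(0, n, D); dQ1 <- matrix(0, n, D)
  dK0 <- matrix(0, n, D); dK1 <- matrix(0, n, D)
  dV0 <- matrix(0, n, D); dV1 <- matrix(0, n, D)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    for (dir in 1:2) {
      A <- if (dir == 1) tc$A0[[h]] else tc$A1[[h]]
      dO <- if (dir == 1) dO0[, idx, drop = FALSE] else dO1[, idx, drop = FALSE]
      Qd <- if (dir == 1) tc$Q0[, idx, drop = FALSE] else tc$Q1[, idx, drop = FALSE]
      dA <- cbind(rowSums(dO * tc$V0[, idx, drop = FALSE]),
                  rowSums(dO * tc$V1[, idx, drop = FALSE]))
      dV0[, idx] <- dV0[, idx] + A[, 1] * dO
      dV1[, idx] <- dV1[, idx] + A[, 2] * dO
      dS <- A * (dA - rowSums(dA * A))
      dQh <- (dS[, 1] * tc$K0[, idx, drop = FALSE] +
                dS[, 2] * tc$K1[, idx, drop = FALSE]) / sqrt(dk)
      if (dir == 1) dQ0[, idx] <- dQ0[, idx] + dQh
      else dQ1[, idx] <- dQ1[, idx] + dQh
      dK0[, idx] <- dK0[, idx] + dS[, 1] * Qd / sqrt(dk)
      dK1[, idx] <- dK1[, idx] + dS[, 2] * Qd / sqrt(dk)
    }
  }
  g$temp$Wq <- g$temp$Wq + t(tc$ln0$y) %*% dQ0 + t(tc$ln1$y) %*% dQ1
  g$temp$Wk <- g$temp$Wk + t(tc$ln0$y) %*% dK0 + t(tc$ln1$y) %*% dK1
  g$temp$Wv <- g$temp$Wv + t(tc$ln0$y) %*% dV0 + t(tc$ln1$y) %*% dV1
  dN0 <- dQ0 %*% t(W$Wq) + dK0 %*% t(W$Wk) + dV0 %*% t(W$Wv)
  dN1 <- dQ1 %*% t(W$Wq) + dK1 %*% t(W$Wk) + dV1 %*% t(W$Wv)
  dX0 <- dX0 + ln_rows_bwd(dN0, tc$ln0)
  dX1 <- dX1 + ln_rows_bwd(dN1, tc$ln1)
  list(dX0 = dX0, dX1 = dX1, g = g)
}

# Gradient of one temporal-fusion block wrt its two input embeddings,
# accumulating the block's weight gradients into g (by reference semantics
# of the returned list).
temporal_backward <- function(dfused, tc, params, config, g) {
  D <- config$embed_dim
  if (tc$mode == "attention") {
    g$cat$W <- g$cat$W + t(tc$cc) %*% matrix(dfused, 1)
    g$cat$b <- g$cat$b + dfused
    dcc <- matrix(dfused, 1) %*% t(params$cat$W)
    b0 <- mha_backward(dcc[, 1:D, drop = FALSE], tc$a0, params$temp)
    b1 <- mha_backward(dcc[, D + 1:D, drop = FALSE], tc$a1, params$temp)
    g$temp <- tree_add(tree_add(b0$dW, b1$dW), g$temp)
    dn0 <- as.numeric(b0$dXq) + b0$dXkv[1, ] + b1$dXkv[1, ]
    dn1 <- as.numeric(b1$dXq) + b0$dXkv[2, ] + b1$dXkv[2, ]
    de0 <- dcc[1, 1:D] + layer_norm_bwd(dn0, tc$ln0)
    de1 <- dcc[1, D + 1:D] + layer_norm_bwd(dn1, tc$ln1)
  } else if (tc$mode == "concatenate") {
    g$fuse_cat$W <- g$fuse_cat$W + t(tc$cc) %*% matrix(dfused, 1)
    g$fuse_cat$b <- g$fuse_cat$b + dfused
    dcc <- matrix(dfused, 1) %*% t(params$fuse_cat$W)
    de0 <- dcc[1, 1:D]
    de1 <- dcc[1, D + 1:D]
  } else {
    g$fuse_sub$W <- g$fuse_sub$W + t(tc$d) %*% matrix(dfused, 1)
    g$fuse_sub$b <- g$fuse_sub$b + dfused
    dd <- as.numeric(matrix(dfused, 1) %*% t(params$fuse_sub$W))
    de0 <- -dd
    de1 <- dd
  }
  list(de0 = de0, de1 = de1, g = g)
}

# Gradient through one spatial-attention block given the gradient of the
# pooled output; returns the token gradients and accumulates weights.
spatial_backward <- function(dpool_vec, sc, tokens_n, params, config, g) {
  D <- config$embed_dim
  dpool <- matrix(dpool_vec / tokens_n, tokens_n, D, byrow = TRUE)
  if (config$ablation$use_spatial_attention) {
    bs <- mha_backward(dpool, sc$mha, params$spat)
    dXn <- bs$dXq + bs$dXkv
    dX <- dpool + t(vapply(seq_len(tokens_n), function(i) {
      layer_norm_bwd(dXn[i, ], sc$ln[[i]])
    }, numeric(D)))
    g$spat <- tree_add(g$spat, bs$dW)
  } else {
    dX <- dpool
  }
  list(dX = dX, g = g)
}

# Backward from dlogit.  Returns the gradient tree for the non-conv
# parameters plus dG per timepoint (gradient at the GAP features, needed
# for encoder fine-tuning and Grad-CAM).
sti_backward_tokens <- function(dlogit, fwd, params, feats, config) {
  cache <- fwd$cache
  regions <- active_regions(config)
  tps <- active_timepoints(config)
  D <- config$embed_dim
  n <- length(regions)
  g <- list(proj = list(W = params$proj$W * 0, b = params$proj$b * 0),
            type_region = params$type_region * 0,
            type_time = params$type_time * 0,
            spat = lapply(params$spat, function(x) x * 0),
            temp = lapply(params$temp, function(x) x * 0),
            cat = list(W = params$cat$W * 0, b = params$cat$b * 0),
            fuse_cat = list(W = params$fuse_cat$W * 0,
                            b = params$fuse_cat$b * 0),
            fuse_sub = list(W = params$fuse_sub$W * 0,
                            b = params$fuse_sub$b * 0),
            head = list(W1 = params$head$W1 * 0, b1 = params$head$b1 * 0,
                        W2 = params$head$W2 * 0, b2 = 0))
  # head
  g$head$b2 <- dlogit
  g$head$W2 <- matrix(cache$h * dlogit, ncol = 1)
  dh <- as.numeric(params$head$W2) * dlogit
  dhpre <- dh * (cache$hpre > 0)
  g$head$W1 <- outer(cache$fln$y, dhpre)
  g$head$b1 <- dhpre
  dfln <- as.numeric(params$head$W1 %*% dhpre)
  dfused <- layer_norm_bwd(dfln, cache$fln$cache)
  if (!is.null(cache$drop_mask)) dfused <- dfused * cache$drop_mask
  dX <- list()
  if (cache$order == "single") {
    sb <- spatial_backward(dfused, cache$spat[[tps]], n, params, config, g)
    g <- sb$g
    dX[[tps]] <- sb$dX
  } else if (cache$order == "temporal_first") {
    sb <- spatial_backward(dfused, cache$spat[["fused"]], n, params,
                           config, g)
    g <- sb$g
    tb <- temporal_first_bwd(sb$dX, cache$temp, params, config, g)
    g <- tb$g
    dX$T0 <- tb$dX0
    dX$T1 <- tb$dX1
  } else {
    tb <- temporal_backward(dfused, cache$temp, params, config, g)
    g <- tb$g
    de <- list(T0 = tb$de0, T1 = tb$de1)
    for (tp in tps) {
      sb <- spatial_backward(de[[tp]], cache$spat[[tp]], n, params, config,
                             g)
      g <- sb$g
      dX[[tp]] <- sb$dX
    }
  }
  # tokens -> proj / type embeddings / features
  dG <- list()
  for (tp in tps) {
    G <- feats[[tp]][regions, , drop = FALSE]
    dXt <- dX[[tp]]
    g$proj$W <- g$proj$W + t(G) %*% dXt
    g$proj$b <- g$proj$b + colSums(dXt)
    for (r in seq_along(regions)) {
      g$type_region[regions[r], ] <- g$type_region[regions[r], ] + dXt[r, ]
    }
    ti <- if (tp == "T0") 1L else 2L
    g$type_time[ti, ] <- g$type_time[ti, ] + colSums(dXt)
    dGfull <- matrix(0, nrow(feats[[tp]]), ncol(feats[[tp]]))
    dGfull[regions, ] <- dXt %*% t(params$proj$W)
    dG[[tp]] <- dGfull
  }
  list(grads = g, dG = dG)
}
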