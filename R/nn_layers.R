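# Small neural-network primitives with explicit forward/backward passes.
# All attention operates on a handful of region/timepoint tokens, so the
# matrices here are tiny; heavy 3D convolution lives in src/sti_ops.cpp.

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# Multi-head attention with queries Xq (nq x D) over keys/values Xkv
# (nk x D):
#   Y = concat_h(softmax(Qh Kh' / sqrt(dk)) Vh) Wo
# The caller adds the residual connection (typically on the raw,
# un-normalized embedding).  Self-attention is the case Xq == Xkv.
mha_forward <- function(Xq, Xkv, W, n_heads) {
  D <- ncol(Xq)
  dk <- D / n_heads
  Q <- Xq %*% W$Wq
  K <- Xkv %*% W$Wk
  V <- Xkv %*% W$Wv
  A <- vector("list", n_heads)
  O <- matrix(0, nrow(Xq), D)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dk)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  Y <- O %*% W$Wo
  list(Y = Y, cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V,
                           A = A, O = O, n_heads = n_heads, dk = dk))
}

# Returns gradients wrt Xq, Xkv and the weight matrices.
mha_backward <- function(dY, cache, W) {
  n_heads <- cache$n_heads
  dk <- cache$dk
  dXq <- dY * 0
  dO <- dY %*% t(W$Wo)
  dWo <- t(cache$O) %*% dY
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))     # softmax Jacobian, rowwise
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) / sqrt(dk)
    dK[, idx] <- (t(dS) %*% cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  list(dXq = dXq + dQ %*% t(W$Wq),
       dXkv = dK %*% t(W$Wk) + dV %*% t(W$Wv),
       dW = list(Wq = t(cache$Xq) %*% dQ,
                 Wk = t(cache$Xkv) %*% dK,
                 Wv = t(cache$Xkv) %*% dV,
                 Wo = dWo))
}

# ---- parameter-tree utilities ----------------------------------------------

# Apply f leaf-wise over parallel numeric trees (named lists of matrices /
# arrays / vectors).
tree_map <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1]]
  if (is.list(first)) {
    out <- lapply(seq_along(first), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(first)
    return(out)
  }
  do.call(f, trees)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map(`+`, a, b)

# One Adam step over a parameter tree; state holds m/v trees and step count.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# Layer normalization of a vector (no learned affine): y = (x - mean) / s
# with s = sqrt(var + eps).  Used at the head input and inside the temporal
# block to keep activations in a trainable range.
layer_norm_fwd <- function(x, eps = 1e-5) {
  mu <- mean(x)
  xc <- x - mu
  s <- sqrt(mean(xc^2) + eps)
  list(y = xc / s, cache = list(y = xc / s, s = s))
}

layer_norm_bwd <- function(dy, cache) {
  y <- cache$y
  (dy - mean(dy) - y * mean(dy * y)) / cache$s
}
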