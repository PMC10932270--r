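# Transformer encoder internals: parameter initialization, forward pass and
# manual backpropagation, written in plain matrix algebra.
#
# Batches are stacked row-wise: a batch of B sequences of T tokens each
# becomes an N x d matrix (N = B * T) whose rows ((b-1)*T + 1) .. (b*T) hold
# sequence b.  Linear layers act on the whole stack through BLAS; only the
# T x T attention products loop over sequences and heads.
#
# Architecture follows post-layer-norm BERT: per layer,
#   X1 = LN1(X + MultiHeadAttention(X));  X2 = LN2(X1 + FFN(X1))
# with GELU feed-forward activation and learned token + position embeddings.

LN_EPS <- 1e-12
ATTN_NEG <- -1e9

gelu_phi <- function(x) stats::pnorm(x)  # cached in the forward pass
gelu <- function(x) x * gelu_phi(x)
# d/dx [x * Phi(x)] = Phi(x) + x * phi(x); phi computed directly from exp
gelu_grad_from_phi <- function(x, phi) phi + x * exp(-0.5 * x * x) * 0.3989422804014327

# broadcast a length-d vector across the rows of an N x d matrix
row_bc <- function(v, n) rep.int(v, rep.int(n, length(v)))

ln_forward <- function(X, g, b) {
  n <- nrow(X); d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  xc <- X - mu
  inv <- 1 / sqrt(.rowMeans(xc * xc, n, d) + LN_EPS)
  xhat <- xc * inv
  list(Y = xhat * row_bc(g, nrow(X)) + row_bc(b, nrow(X)),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  n <- nrow(dY); d <- ncol(dY)
  dxhat <- dY * row_bc(g, n)
  dg <- .colSums(dY * cache$xhat, n, d)
  db <- .colSums(dY, n, d)
  m1 <- .rowMeans(dxhat, n, d)
  m2 <- .rowMeans(dxhat * cache$xhat, n, d)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

init_layer_params <- function(d, dff, sd = 0.02) {
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  list(Wq = rn(d, d), bq = numeric(d), Wk = rn(d, d), bk = numeric(d),
       Wv = rn(d, d), bv = numeric(d), Wo = rn(d, d), bo = numeric(d),
       ln1_g = rep(1, d), ln1_b = numeric(d),
       W1 = rn(d, dff), b1 = numeric(dff), W2 = rn(dff, d), b2 = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

# Forward pass of the encoder stack over one tokenized batch.
# ids: B x T matrix of 0-based token ids; mask: B x T of 0/1.
# perturb: optional N x d matrix added to the embedding output (FGM).
encoder_forward <- function(params, cfg, ids, mask, scale_key,
                            perturb = NULL, want_attn = FALSE,
                            want_cache = FALSE, pooling = "cls") {
  B <- nrow(ids); T_ <- ncol(ids); N <- B * T_
  d <- cfg$hidden_dim; H <- cfg$n_heads; dh <- d %/% H
  if (T_ > cfg$max_tokens) {
    stop2("token stream length ", T_, " exceeds max_tokens = ", cfg$max_tokens)
  }
  emb <- params$emb[[scale_key]]
  if (max(ids) + 1L > nrow(emb)) {
    stop2("token id ", max(ids), " out of range for vocabulary of size ",
          nrow(emb))
  }
  idx <- as.vector(t(ids)) + 1L
  pos_idx <- rep(seq_len(T_), times = B)
  E <- emb[idx, , drop = FALSE] + params$pos[pos_idx, , drop = FALSE]
  if (!is.null(perturb)) E <- E + perturb
  X <- E
  scale <- 1 / sqrt(dh)
  keep <- want_cache
  layer_caches <- if (keep) vector("list", cfg$n_layers)
  attns <- if (want_attn) vector("list", cfg$n_layers)
  row_blocks <- lapply(seq_len(B), function(b) ((b - 1L) * T_ + 1L):(b * T_))
  col_blocks <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  # additive key bias per sequence; NULL when the sequence has no padding
  key_bias <- lapply(seq_len(B), function(b) {
    if (all(mask[b, ] == 1L)) return(NULL)
    bias <- numeric(T_)
    bias[mask[b, ] == 0L] <- ATTN_NEG
    row_bc(bias, T_)
  })
  rmax_idx <- seq_len(T_)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    Xin <- X
    QKV <- Xin %*% cbind(lp$Wq, lp$Wk, lp$Wv) +
      row_bc(c(lp$bq, lp$bk, lp$bv), N)
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, (d + 1L):(2L * d), drop = FALSE]
    V <- QKV[, (2L * d + 1L):(3L * d), drop = FALSE]
    AO <- matrix(0, N, d)
    P_store <- if (keep || want_attn) vector("list", B)
    for (b in seq_len(B)) {
      rb <- row_blocks[[b]]
      Qb <- Q[rb, , drop = FALSE]
      Kb <- K[rb, , drop = FALSE]
      Vb <- V[rb, , drop = FALSE]
      Ob <- matrix(0, T_, d)
      Pb <- if (keep || want_attn) vector("list", H)
      for (h in seq_len(H)) {
        ch <- col_blocks[[h]]
        S <- tcrossprod(Qb[, ch, drop = FALSE], Kb[, ch, drop = FALSE]) * scale
        if (!is.null(key_bias[[b]])) S <- S + key_bias[[b]]
        S <- S - S[cbind(rmax_idx, max.col(S, "first"))]
        P <- exp(S)
        P <- P / .rowSums(P, T_, T_)
        Ob[, ch] <- P %*% Vb[, ch, drop = FALSE]
        if (!is.null(Pb)) Pb[[h]] <- P
      }
      AO[rb, ] <- Ob
      if (!is.null(Pb)) P_store[[b]] <- Pb
    }
    A <- AO %*% lp$Wo + row_bc(lp$bo, N)
    R1 <- Xin + A
    ln1 <- ln_forward(R1, lp$ln1_g, lp$ln1_b)
    X1 <- ln1$Y
    H1 <- X1 %*% lp$W1 + row_bc(lp$b1, N)
    Phi <- gelu_phi(H1)
    G <- H1 * Phi
    Fo <- G %*% lp$W2 + row_bc(lp$b2, N)
    ln2 <- ln_forward(X1 + Fo, lp$ln2_g, lp$ln2_b)
    X <- ln2$Y
    if (keep) {
      layer_caches[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, P = P_store,
                                AO = AO, ln1 = ln1, X1 = X1, H1 = H1, G = G,
                                Phi = Phi, ln2 = ln2)
    }
    if (want_attn) attns[[l]] <- P_store
  }
  cls_rows <- seq(1L, N, by = T_)
  pooled <- if (pooling == "cls") {
    X[cls_rows, , drop = FALSE]
  } else {
    mvec <- as.vector(t(mask))
    sums <- rowsum(X * mvec, group = rep(seq_len(B), each = T_))
    sums / rowSums(mask)
  }
  list(X = X, pooled = pooled, cls_rows = cls_rows,
       B = B, T = T_, idx = idx, pos_idx = pos_idx,
       mask = mask, scale_key = scale_key,
       cache = layer_caches, attn = attns,
       row_blocks = row_blocks, col_blocks = col_blocks)
}

# Backpropagate through an encoder_forward() run with want_cache = TRUE.
# dX: N x d gradient at the final hidden states (may be NULL);
# dpooled: B x d gradient at the pooled vector.
# Returns per-parameter gradients plus dE, the gradient at the embedding
# output (the FGM "sequence representation" gradient).
encoder_backward <- function(dX, dpooled, fw, params, cfg, pooling = "cls") {
  B <- fw$B; T_ <- fw$T; N <- B * T_
  d <- cfg$hidden_dim; H <- cfg$n_heads; dh <- d %/% H
  scale <- 1 / sqrt(dh)
  if (is.null(dX)) dX <- matrix(0, N, d)
  if (!is.null(dpooled)) {
    if (pooling == "cls") {
      dX[fw$cls_rows, ] <- dX[fw$cls_rows, ] + dpooled
    } else {
      mvec <- as.vector(t(fw$mask))
      lens <- rowSums(fw$mask)
      dX <- dX + (dpooled / lens)[rep(seq_len(B), each = T_), ] * mvec
    }
  }
  g_layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    cc <- fw$cache[[l]]
    bl2 <- ln_backward(dX, cc$ln2, lp$ln2_g)
    dR2 <- bl2$dX
    dG <- dR2 %*% t(lp$W2)
    dW2 <- crossprod(cc$G, dR2)
    db2 <- colSums(dR2)
    dH1 <- dG * gelu_grad_from_phi(cc$H1, cc$Phi)
    dW1 <- crossprod(cc$X1, dH1)
    db1 <- colSums(dH1)
    dX1 <- dR2 + dH1 %*% t(lp$W1)
    bl1 <- ln_backward(dX1, cc$ln1, lp$ln1_g)
    dR1 <- bl1$dX
    dAO <- dR1 %*% t(lp$Wo)
    dWo <- crossprod(cc$AO, dR1)
    dbo <- colSums(dR1)
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (b in seq_len(B)) {
      rb <- fw$row_blocks[[b]]
      Pb <- cc$P[[b]]
      dAb <- dAO[rb, , drop = FALSE]
      Kb <- cc$K[rb, , drop = FALSE]
      Qb <- cc$Q[rb, , drop = FALSE]
      Vb <- cc$V[rb, , drop = FALSE]
      dQb <- matrix(0, T_, d); dKb <- matrix(0, T_, d); dVb <- matrix(0, T_, d)
      for (h in seq_len(H)) {
        ch <- fw$col_blocks[[h]]
        P <- Pb[[h]]
        dOb <- dAb[, ch, drop = FALSE]
        dVb[, ch] <- crossprod(P, dOb)
        dP <- tcrossprod(dOb, Vb[, ch, drop = FALSE])
        dS <- P * (dP - .rowSums(dP * P, T_, T_)) * scale
        dQb[, ch] <- dS %*% Kb[, ch, drop = FALSE]
        dKb[, ch] <- crossprod(dS, Qb[, ch, drop = FALSE])
      }
      dQ[rb, ] <- dQb; dK[rb, ] <- dKb; dV[rb, ] <- dVb
    }
    dQKV <- cbind(dQ, dK, dV)
    dWqkv <- crossprod(cc$Xin, dQKV)
    dWq <- dWqkv[, 1:d, drop = FALSE]
    dWk <- dWqkv[, (d + 1L):(2L * d), drop = FALSE]
    dWv <- dWqkv[, (2L * d + 1L):(3L * d), drop = FALSE]
    dbq <- colSums(dQ); dbk <- colSums(dK); dbv <- colSums(dV)
    dX <- dR1 + dQKV %*% t(cbind(lp$Wq, lp$Wk, lp$Wv))
    g_layers[[l]] <- list(Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                          Wv = dWv, bv = dbv, Wo = dWo, bo = dbo,
                          ln1_g = bl1$dg, ln1_b = bl1$db,
                          W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                          ln2_g = bl2$dg, ln2_b = bl2$db)
  }
  demb <- matrix(0, nrow(params$emb[[fw$scale_key]]), d)
  rs <- rowsum(dX, group = fw$idx)
  demb[as.integer(rownames(rs)), ] <- rs
  dpos <- matrix(0, nrow(params$pos), d)
  rs <- rowsum(dX, group = fw$pos_idx)
  dpos[as.integer(rownames(rs)), ] <- rs
  list(layers = g_layers, emb = demb, pos = dpos, dE = dX)
}

# ---- Adam optimizer over nested gradient trees -------------------------

tree_zero <- function(g) {
  if (is.list(g)) lapply(g, tree_zero) else g * 0
}

# iterate a nested list by names when present (subtree selection against a
# larger parameter tree), by position otherwise (e.g. the per-layer list)
tree_keys <- function(x) {
  if (!is.null(names(x)) && all(nzchar(names(x)))) names(x) else seq_along(x)
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    out <- a
    for (kk in tree_keys(a)) out[[kk]] <- tree_add(a[[kk]], b[[kk]])
    out
  } else a + b
}

adam_init <- function(grads) list(m = tree_zero(grads), v = tree_zero(grads), t = 0L)

adam_update_tree <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.list(g)) {
    for (kk in tree_keys(g)) {
      upd <- adam_update_tree(p[[kk]], g[[kk]], m[[kk]], v[[kk]],
                              lr_t, beta1, beta2, eps)
      p[[kk]] <- upd$p; m[[kk]] <- upd$m; v[[kk]] <- upd$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    list(p = p - lr_t * m / (sqrt(v) + eps), m = m, v = v)
  }
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  upd <- adam_update_tree(params, grads, state$m, state$v,
                          lr_t, beta1, beta2, eps)
  list(params = upd$p, state = list(m = upd$m, v = upd$v, t = state$t))
}
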