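# Internal neural-network primitives: forward passes paired with explicit
# backward passes (reverse-mode, hand-derived). Parameters live in a flat
# named list of matrices/vectors; each *_fwd returns list(y, cache) and each
# *_bwd consumes (dy, cache) and returns gradients. Correctness is pinned by
# a finite-difference gradient check in the test suite.

MASK_NEG <- -1e30  # additive mask logit; exp() underflows to exactly 0

rmat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)

# orthonormal init (rows or columns orthonormal depending on shape)
ortho_init <- function(nr, nc) {
  if (nr >= nc) qr.Q(qr(matrix(rnorm(nr * nc), nr, nc)))
  else t(qr.Q(qr(matrix(rnorm(nr * nc), nc, nr))))
}

add_rowvec <- function(x, b) sweep(x, 2, b, "+")

## ---- layer norm (per row over channels) ----

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_rowvec(sweep(xhat, 2, g, "*"), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## ---- GELU (exact, Phi-based) ----

gelu_fwd <- function(x) list(y = x * pnorm(x), cache = x)
gelu_bwd <- function(dy, cache) dy * (pnorm(cache) + cache * dnorm(cache))

## ---- multi-head attention ----
# q: Lq x D queries, kv: Lk x D keys/values (same tensor used for K and V).
# key_mask: length-Lk 0/1; masked keys get exactly zero attention weight.
# rb: optional n_heads x (2R+1) relative-position bias, indexed by rel_idx
# (Lq x Lk integer matrix into 1..2R+1).

mha_fwd <- function(q, kv, W, key_mask, n_heads, rb = NULL, rel_idx = NULL) {
  D <- ncol(q)
  dh <- D %/% n_heads
  if (!any(key_mask > 0)) cheap_abort("all key positions are masked out.",
                                      "cheap_all_masked")
  Q <- add_rowvec(q %*% W$Wq, W$bq)
  K <- add_rowvec(kv %*% W$Wk, W$bk)
  V <- add_rowvec(kv %*% W$Wv, W$bv)
  Lq <- nrow(q)
  O <- matrix(0, Lq, D)
  A_list <- vector("list", n_heads)
  masked <- key_mask == 0
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(rb)) S <- S + matrix(rb[h, rel_idx], Lq)
    S[, masked] <- MASK_NEG
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  y <- add_rowvec(O %*% W$Wo, W$bo)
  list(y = y,
       cache = list(q = q, kv = kv, Q = Q, K = K, V = V, O = O, A = A_list,
                    W = W, n_heads = n_heads, dh = dh, rel_idx = rel_idx,
                    has_rb = !is.null(rb)))
}

mha_bwd <- function(dy, cache) {
  W <- cache$W; nh <- cache$n_heads; dh <- cache$dh
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- tcrossprod(dy, W$Wo)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  drb <- NULL
  if (cache$has_rb) drb <- matrix(0, nh, max(cache$rel_idx))
  for (h in seq_len(nh)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))  # masked columns have A=0, hence dS=0
    if (cache$has_rb) {
      acc <- rowsum(as.vector(dS), as.vector(cache$rel_idx))
      drb[h, as.integer(rownames(acc))] <- drb[h, as.integer(rownames(acc))] + acc[, 1]
    }
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(dq = tcrossprod(dQ, W$Wq),
       dkv = tcrossprod(dK, W$Wk) + tcrossprod(dV, W$Wv),
       dWq = crossprod(cache$q, dQ), dbq = colSums(dQ),
       dWk = crossprod(cache$kv, dK), dbk = colSums(dK),
       dWv = crossprod(cache$kv, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo, drb = drb)
}

## ---- transformer block (pre-norm, GELU FFN, learned relative bias) ----

init_block <- function(D, n_heads, ffn_mult, rel_window) {
  H <- D * ffn_mult
  list(ln1_g = rep(1, D), ln1_b = rep(0, D),
       Wq = rmat(D, D), bq = rep(0, D), Wk = rmat(D, D), bk = rep(0, D),
       Wv = rmat(D, D), bv = rep(0, D), Wo = rmat(D, D), bo = rep(0, D),
       rb = matrix(0, n_heads, 2 * rel_window + 1),
       ln2_g = rep(1, D), ln2_b = rep(0, D),
       W1 = rmat(D, H), b1 = rep(0, H), W2 = rmat(H, D), b2 = rep(0, D))
}

# self-attention rel index: clip(j - i, -R, R) + R + 1
rel_index <- function(L, R) {
  rel <- outer(seq_len(L), seq_len(L), function(i, j) pmin(pmax(j - i, -R), R))
  rel + R + 1L
}

block_fwd <- function(p, pre, x, m, n_heads, rel_window) {
  g <- function(nm) p[[paste0(pre, nm)]]
  L <- nrow(x)
  ln1 <- ln_fwd(x, g("ln1_g"), g("ln1_b"))
  att <- mha_fwd(ln1$y, ln1$y,
                 list(Wq = g("Wq"), bq = g("bq"), Wk = g("Wk"), bk = g("bk"),
                      Wv = g("Wv"), bv = g("bv"), Wo = g("Wo"), bo = g("bo")),
                 key_mask = m, n_heads = n_heads,
                 rb = g("rb"), rel_idx = rel_index(L, rel_window))
  x2 <- x + att$y
  ln2 <- ln_fwd(x2, g("ln2_g"), g("ln2_b"))
  h <- add_rowvec(ln2$y %*% g("W1"), g("b1"))
  ge <- gelu_fwd(h)
  f <- add_rowvec(ge$y %*% g("W2"), g("b2"))
  y <- (x2 + f) * m  # re-zero padded rows: pad content never leaks forward
  list(y = y, cache = list(ln1 = ln1, att = att, ln2 = ln2, ge = ge,
                           m = m, pre = pre, ln2y = ln2$y))
}

block_bwd <- function(p, dy, cache, grads) {
  pre <- cache$pre
  g <- function(nm) p[[paste0(pre, nm)]]
  add <- function(nm, val) {
    key <- paste0(pre, nm)
    grads[[key]] <<- if (is.null(grads[[key]])) val else grads[[key]] + val
  }
  dy <- dy * cache$m
  # FFN branch
  dW2 <- crossprod(cache$ge$y, dy); db2 <- colSums(dy)
  dge <- tcrossprod(dy, g("W2"))
  dh <- gelu_bwd(dge, cache$ge$cache)
  dW1 <- crossprod(cache$ln2y, dh)
  db1 <- colSums(dh)
  dln2y <- tcrossprod(dh, g("W1"))
  bl2 <- ln_bwd(dln2y, cache$ln2$cache)
  dx2 <- dy + bl2$dx
  # attention branch
  ab <- mha_bwd(dx2, cache$att$cache)
  dln1y <- ab$dq + ab$dkv
  bl1 <- ln_bwd(dln1y, cache$ln1$cache)
  dx <- dx2 + bl1$dx
  add("ln1_g", bl1$dg); add("ln1_b", bl1$db)
  add("Wq", ab$dWq); add("bq", ab$dbq); add("Wk", ab$dWk); add("bk", ab$dbk)
  add("Wv", ab$dWv); add("bv", ab$dbv); add("Wo", ab$dWo); add("bo", ab$dbo)
  add("rb", ab$drb)
  add("ln2_g", bl2$dg); add("ln2_b", bl2$db)
  add("W1", dW1); add("b1", db1); add("W2", dW2); add("b2", db2)
  list(dx = dx, grads = grads)
}

## ---- attention-resampling layer (residual cross-attention, pre-norm) ----

init_resample <- function(D, n_heads) {
  list(lnq_g = rep(1, D), lnq_b = rep(0, D), lnk_g = rep(1, D), lnk_b = rep(0, D),
       Wq = rmat(D, D), bq = rep(0, D), Wk = rmat(D, D), bk = rep(0, D),
       Wv = rmat(D, D), bv = rep(0, D), Wo = rmat(D, D), bo = rep(0, D))
}

resample_fwd <- function(p, pre, q, kv, key_mask, q_mask, n_heads) {
  g <- function(nm) p[[paste0(pre, nm)]]
  lnq <- ln_fwd(q, g("lnq_g"), g("lnq_b"))
  lnk <- ln_fwd(kv, g("lnk_g"), g("lnk_b"))
  att <- mha_fwd(lnq$y, lnk$y,
                 list(Wq = g("Wq"), bq = g("bq"), Wk = g("Wk"), bk = g("bk"),
                      Wv = g("Wv"), bv = g("bv"), Wo = g("Wo"), bo = g("bo")),
                 key_mask = key_mask, n_heads = n_heads)
  y <- (q + att$y) * q_mask
  list(y = y, cache = list(lnq = lnq, lnk = lnk, att = att,
                           q_mask = q_mask, pre = pre))
}

resample_bwd <- function(p, dy, cache, grads) {
  pre <- cache$pre
  add <- function(nm, val) {
    key <- paste0(pre, nm)
    grads[[key]] <<- if (is.null(grads[[key]])) val else grads[[key]] + val
  }
  dy <- dy * cache$q_mask
  ab <- mha_bwd(dy, cache$att$cache)
  blq <- ln_bwd(ab$dq, cache$lnq$cache)
  blk <- ln_bwd(ab$dkv, cache$lnk$cache)
  add("lnq_g", blq$dg); add("lnq_b", blq$db)
  add("lnk_g", blk$dg); add("lnk_b", blk$db)
  add("Wq", ab$dWq); add("bq", ab$dbq); add("Wk", ab$dWk); add("bk", ab$dbk)
  add("Wv", ab$dWv); add("bv", ab$dbv); add("Wo", ab$dWo); add("bo", ab$dbo)
  list(dq = dy + blq$dx, dkv = blk$dx, grads = grads)
}

## ---- AdamW (decoupled weight decay, linear warmup then constant) ----

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm * gnm
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decay weight matrices only, not gains/biases/codebooks
    if (grepl("(^|_)W", nm)) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# learning-rate schedule: linear warmup to `lr`, constant afterwards
lr_at_step <- function(step, lr, warmup_steps) {
  if (warmup_steps <= 0) return(lr)
  lr * min(1, step / warmup_steps)
}
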