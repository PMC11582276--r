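# Low-level network primitives with explicit forward/backward passes.
#
# Parameters live in a flat environment keyed by dotted paths
# ("blk3.Wo", "sc1.bma.tau", ...). Gradients are accumulated into a parallel
# environment by the *_bwd functions. All forward functions return
# list(out, cache); backward functions take the upstream gradient plus the
# cache and return the gradient w.r.t. their input.

acc_add <- function(acc, name, g) {
  cur <- acc[[name]]
  acc[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# y = x W + b for row-token matrices
lin_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- y + rep(b, each = nrow(y))   # column-major broadcast of the bias
  list(out = y, x = x)
}

lin_bwd <- function(dy, cache, W, acc, nm_W, nm_b) {
  acc_add(acc, nm_W, crossprod(cache$x, dy))
  acc_add(acc, nm_b, colSums(dy))
  dy %*% t(W)
}

LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  n <- nrow(x)
  y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g, acc, nm_g, nm_b) {
  xhat <- cache$xhat
  acc_add(acc, nm_g, colSums(dy * xhat))
  acc_add(acc, nm_b, colSums(dy))
  dxh <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  (dxh - m1 - xhat * m2) * cache$inv
}

gelu_fwd <- function(x) list(out = x * stats::pnorm(x), x = x)
gelu_bwd <- function(dy, cache) {
  x <- cache$x
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

# Multi-head attention with learnable per-head softmax temperature and
# optional diagonal masking, followed by residual + layer norm and an MLP
# with residual + layer norm (post-norm ordering). Self-attention when
# kv is NULL; cross-attention (queries from x, keys/values from kv)
# otherwise. The attention logits are Q K^T scaled only by the learnable
# temperature tau (initialized at sqrt(head_dim)).
attn_block_fwd <- function(x, P, pre, heads, mask_diag = TRUE, kv = NULL) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  n <- nrow(x); C <- ncol(x)
  hd <- C %/% heads
  cross <- !is.null(kv)
  if (cross) {
    lq <- lin_fwd(x, g("Wq"), g("bq"))
    lkv <- lin_fwd(kv, g("Wkv"), g("bkv"))
    Q <- lq$out
    K <- lkv$out[, 1:C, drop = FALSE]
    V <- lkv$out[, (C + 1):(2 * C), drop = FALSE]
    m <- nrow(kv)
  } else {
    lq <- lin_fwd(x, g("Wqkv"), g("bqkv"))
    Q <- lq$out[, 1:C, drop = FALSE]
    K <- lq$out[, (C + 1):(2 * C), drop = FALSE]
    V <- lq$out[, (2 * C + 1):(3 * C), drop = FALSE]
    m <- n
  }
  tau <- pmax(g("tau"), 1e-4)
  if (any(g("tau") <= 0))
    warning("non-positive attention temperature clamped to 1e-4")
  O <- matrix(0, n, C)
  hcache <- vector("list", heads)
  for (h in seq_len(heads)) {
    ix <- ((h - 1) * hd + 1):(h * hd)
    A <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE])
    Z <- A / tau[h]
    if (mask_diag) diag(Z) <- -Inf
    Z <- Z - Z[cbind(seq_len(n), max.col(Z, ties.method = "first"))]
    E <- exp(Z)
    Pm <- E / rowSums(E)
    O[, ix] <- Pm %*% V[, ix, drop = FALSE]
    Am <- A
    if (mask_diag) diag(Am) <- 0   # masked logits carry no gradient
    hcache[[h]] <- list(P = Pm, A = Am)
  }
  lo <- lin_fwd(O, g("Wo"), g("bo"))
  r1 <- x + lo$out
  n1 <- ln_fwd(r1, g("ln1_g"), g("ln1_b"))
  l1 <- lin_fwd(n1$out, g("W1"), g("b1"))
  a1 <- gelu_fwd(l1$out)
  l2 <- lin_fwd(a1$out, g("W2"), g("b2"))
  r2 <- n1$out + l2$out
  n2 <- ln_fwd(r2, g("ln2_g"), g("ln2_b"))
  list(out = n2$out,
       cache = list(lq = lq, lkv = if (cross) lkv, hcache = hcache,
                    lo = lo, n1 = n1, l1 = l1, a1 = a1, l2 = l2, n2 = n2,
                    Q = Q, K = K, V = V, tau = tau, cross = cross,
                    mask = mask_diag, heads = heads, hd = hd, C = C))
}

attn_block_bwd <- function(dy, cache, P, pre, acc) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  nm <- function(s) paste0(pre, ".", s)
  C <- cache$C; heads <- cache$heads; hd <- cache$hd
  dr2 <- ln_bwd(dy, cache$n2, g("ln2_g"), acc, nm("ln2_g"), nm("ln2_b"))
  da1 <- lin_bwd(dr2, cache$l2, g("W2"), acc, nm("W2"), nm("b2"))
  dl1 <- gelu_bwd(da1, cache$a1)
  dn1 <- lin_bwd(dl1, cache$l1, g("W1"), acc, nm("W1"), nm("b1")) + dr2
  dr1 <- ln_bwd(dn1, cache$n1, g("ln1_g"), acc, nm("ln1_g"), nm("ln1_b"))
  dO <- lin_bwd(dr1, cache$lo, g("Wo"), acc, nm("Wo"), nm("bo"))
  Q <- cache$Q; K <- cache$K; V <- cache$V; tau <- cache$tau
  dQ <- matrix(0, nrow(Q), C)
  dK <- matrix(0, nrow(K), C)
  dV <- matrix(0, nrow(K), C)
  dtau <- numeric(heads)
  for (h in seq_len(heads)) {
    ix <- ((h - 1) * hd + 1):(h * hd)
    hc <- cache$hcache[[h]]
    Pm <- hc$P
    dOh <- dO[, ix, drop = FALSE]
    dP <- tcrossprod(dOh, V[, ix, drop = FALSE])
    dV[, ix] <- crossprod(Pm, dOh)
    dZ <- Pm * (dP - rowSums(dP * Pm))
    dA <- dZ / tau[h]
    dtau[h] <- -sum(dZ * hc$A) / tau[h]^2
    dQ[, ix] <- dA %*% K[, ix, drop = FALSE]
    dK[, ix] <- crossprod(dA, Q[, ix, drop = FALSE])
  }
  acc_add(acc, nm("tau"), dtau)
  if (cache$cross) {
    dx <- lin_bwd(dQ, cache$lq, g("Wq"), acc, nm("Wq"), nm("bq")) + dr1
    lin_bwd(cbind(dK, dV), cache$lkv, g("Wkv"), acc, nm("Wkv"), nm("bkv"))
    dx
  } else {
    lin_bwd(cbind(dQ, dK, dV), cache$lq, g("Wqkv"), acc,
            nm("Wqkv"), nm("bqkv")) + dr1
  }
}

# Latent compression of a row-major (h*w) x C patch-token grid:
# width-3 stride-1 average pooling along each grid row (w -> w-2), then
# channel concatenation of adjacent row pairs projected 2C -> C
# (h -> h/2). Output grid (h/2) x (w-2), row-major.
lc_fwd <- function(patch, grid, P, pre) {
  h <- grid[1]; w <- grid[2]; C <- ncol(patch)
  if (h %% 2L != 0L) stop("latent compression needs an even grid height, got ", h)
  if (w < 3L) stop("latent compression needs grid width >= 3, got ", w)
  Wc <- P[[paste0(pre, ".Wc")]]; bc <- P[[paste0(pre, ".bc")]]
  wp <- w - 2L
  pooled <- matrix(0, h * wp, C)
  for (i in seq_len(h)) {
    sub <- patch[((i - 1) * w + 1):(i * w), , drop = FALSE]
    pooled[((i - 1) * wp + 1):(i * wp), ] <-
      (sub[1:wp, , drop = FALSE] + sub[2:(wp + 1), , drop = FALSE] +
         sub[3:w, , drop = FALSE]) / 3
  }
  h2 <- h %/% 2L
  cat2 <- matrix(0, h2 * wp, 2 * C)
  for (i in seq_len(h2)) {
    r1 <- ((2 * i - 2) * wp + 1):((2 * i - 1) * wp)
    r2 <- ((2 * i - 1) * wp + 1):((2 * i) * wp)
    cat2[((i - 1) * wp + 1):(i * wp), ] <-
      cbind(pooled[r1, , drop = FALSE], pooled[r2, , drop = FALSE])
  }
  lc <- lin_fwd(cat2, Wc, bc)
  list(out = lc$out, cache = list(lc = lc, h = h, w = w, wp = wp, C = C),
       grid = c(h2, wp))
}

lc_bwd <- function(dy, cache, P, pre, acc) {
  Wc <- P[[paste0(pre, ".Wc")]]
  dcat <- lin_bwd(dy, cache$lc, Wc, acc, paste0(pre, ".Wc"),
                  paste0(pre, ".bc"))
  h <- cache$h; w <- cache$w; wp <- cache$wp; C <- cache$C
  h2 <- h %/% 2L
  dpooled <- matrix(0, h * wp, C)
  for (i in seq_len(h2)) {
    rows <- ((i - 1) * wp + 1):(i * wp)
    dpooled[((2 * i - 2) * wp + 1):((2 * i - 1) * wp), ] <-
      dcat[rows, 1:C, drop = FALSE]
    dpooled[((2 * i - 1) * wp + 1):((2 * i) * wp), ] <-
      dcat[rows, (C + 1):(2 * C), drop = FALSE]
  }
  dpatch <- matrix(0, h * w, C)
  for (i in seq_len(h)) {
    dp <- dpooled[((i - 1) * wp + 1):(i * wp), , drop = FALSE] / 3
    base <- (i - 1) * w
    for (s in 0:2) {
      rows <- (base + 1 + s):(base + wp + s)
      dpatch[rows, ] <- dpatch[rows, , drop = FALSE] + dp
    }
  }
  dpatch
}

# scalar regression head: C -> hidden -> 1 MLP with GELU
head_fwd <- function(v, P, pre) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  x <- matrix(v, 1)
  l1 <- lin_fwd(x, g("W1"), g("b1"))
  a1 <- gelu_fwd(l1$out)
  l2 <- lin_fwd(a1$out, g("W2"), g("b2"))
  list(out = drop(l2$out), cache = list(l1 = l1, a1 = a1, l2 = l2))
}

head_bwd <- function(dout, cache, P, pre, acc) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  nm <- function(s) paste0(pre, ".", s)
  da1 <- lin_bwd(matrix(dout, 1), cache$l2, g("W2"), acc, nm("W2"), nm("b2"))
  dl1 <- gelu_bwd(da1, cache$a1)
  drop(lin_bwd(dl1, cache$l1, g("W1"), acc, nm("W1"), nm("b1")))
}
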