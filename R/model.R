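# Parameter initialization, the FF-PE feature path, and the assembled
# forward/backward passes of the FF-ViT orientation regressor.

init_w <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)

init_attn_params <- function(P, pre, C, mlp_dim, heads, cross = FALSE) {
  if (cross) {
    P[[paste0(pre, ".Wq")]] <- init_w(C, C)
    P[[paste0(pre, ".bq")]] <- numeric(C)
    P[[paste0(pre, ".Wkv")]] <- init_w(C, 2 * C)
    P[[paste0(pre, ".bkv")]] <- numeric(2 * C)
  } else {
    P[[paste0(pre, ".Wqkv")]] <- init_w(C, 3 * C)
    P[[paste0(pre, ".bqkv")]] <- numeric(3 * C)
  }
  P[[paste0(pre, ".Wo")]] <- init_w(C, C)
  P[[paste0(pre, ".bo")]] <- numeric(C)
  P[[paste0(pre, ".tau")]] <- rep(sqrt(C / heads), heads)
  P[[paste0(pre, ".ln1_g")]] <- rep(1, C)
  P[[paste0(pre, ".ln1_b")]] <- numeric(C)
  P[[paste0(pre, ".W1")]] <- init_w(C, mlp_dim)
  P[[paste0(pre, ".b1")]] <- numeric(mlp_dim)
  P[[paste0(pre, ".W2")]] <- init_w(mlp_dim, C)
  P[[paste0(pre, ".b2")]] <- numeric(C)
  P[[paste0(pre, ".ln2_g")]] <- rep(1, C)
  P[[paste0(pre, ".ln2_b")]] <- numeric(C)
  invisible(NULL)
}

#' Initialize FF-ViT parameters
#'
#' Allocates and initializes every learnable parameter of the model described
#' by `config`: the FF-PE embedding (layer norm + linear projection + cls
#' token), the shared learnable position vector, `depth` backbone
#' self-attention blocks, and per pyramid scale a blur-mapping cross-attention
#' block, `sa_per_scale` self-attention blocks, a latent-compression
#' projection (while compressions remain) and two MLP regression heads.
#' Weights are N(0, 0.02^2); the cls token and position vector are N(0, 1);
#' attention temperatures start at sqrt(head_dim).
#'
#' @param config an [ffvit_config()].
#' @param seed integer seed for reproducible initialization.
#' @return an environment of parameter arrays keyed by dotted module path.
#' @export
ffvit_init <- function(config, seed = 1L) {
  P <- new.env(parent = emptyenv())
  C <- config$dim
  with_seed(seed, {
    D <- config$patch_feat
    P[["ffpe.ln_g"]] <- rep(1, D)
    P[["ffpe.ln_b"]] <- numeric(D)
    P[["ffpe.W"]] <- init_w(D, C)
    P[["ffpe.b"]] <- numeric(C)
    P[["ffpe.cls"]] <- stats::rnorm(C)
    P[["vp"]] <- stats::rnorm(C)
    for (i in seq_len(config$depth))
      init_attn_params(P, paste0("blk", i), C, config$mlp_dim, config$heads)
    for (s in seq_len(config$n_scales)) {
      init_attn_params(P, paste0("sc", s, ".bma"), C, config$mlp_dim,
                       config$heads, cross = TRUE)
      for (j in seq_len(config$sa_per_scale))
        init_attn_params(P, paste0("sc", s, ".sa", j), C, config$mlp_dim,
                         config$heads)
      if (s <= config$lc_layers) {
        P[[paste0("sc", s, ".lc.Wc")]] <- init_w(2 * C, C)
        P[[paste0("sc", s, ".lc.bc")]] <- numeric(C)
      }
      for (hn in c("hp", "hc")) {
        P[[paste0("sc", s, ".", hn, ".W1")]] <- init_w(C, config$mlp_dim)
        P[[paste0("sc", s, ".", hn, ".b1")]] <- numeric(config$mlp_dim)
        P[[paste0("sc", s, ".", hn, ".W2")]] <- init_w(config$mlp_dim, 1)
        P[[paste0("sc", s, ".", hn, ".b2")]] <- numeric(1)
      }
    }
  })
  P
}

#' Count trainable parameters
#'
#' @param params a parameter environment from [ffvit_init()].
#' @return total number of scalar trainable parameters.
#' @export
ffvit_n_params <- function(params) {
  sum(vapply(ls(params), function(nm) length(params[[nm]]), numeric(1)))
}

#' Spatial-shift augmentation
#'
#' Stacks the input frame with four 1-step shifted copies (up, down, left,
#' right), zero-filled at the vacated borders, giving the 5-channel input of
#' the frequency-domain patch embedding.
#'
#' @param image H x W numeric matrix.
#' @param shift_px shift in pixels (>= 1, < min(H, W)).
#' @return 5 x H x W array, channels ordered
#'   `original, up, down, left, right`.
#' @export
spatial_shift_augment <- function(image, shift_px = 1L) {
  s <- as.integer(shift_px)
  h <- nrow(image); w <- ncol(image)
  if (s < 1L) stop("shift_px must be >= 1")
  if (s >= min(h, w)) stop("shift_px must be smaller than both image dimensions")
  z <- function() matrix(0, h, w)
  up <- z();    up[1:(h - s), ] <- image[(s + 1):h, ]
  down <- z();  down[(s + 1):h, ] <- image[1:(h - s), ]
  left <- z();  left[, 1:(w - s)] <- image[, (s + 1):w]
  right <- z(); right[, (s + 1):w] <- image[, 1:(w - s)]
  out <- array(0, c(5, h, w))
  out[1, , ] <- image; out[2, , ] <- up; out[3, , ] <- down
  out[4, , ] <- left; out[5, , ] <- right
  out
}

#' Partition a channel stack into non-overlapping patches
#'
#' @param stack `ch x H x W` array.
#' @param patch_hw integer(2) patch height/width; must divide H and W.
#' @return `Np x ch x Hp x Wp` array, patches ordered row-major over the
#'   patch grid.
#' @export
patch_partition <- function(stack, patch_hw) {
  ch <- dim(stack)[1]; h <- dim(stack)[2]; w <- dim(stack)[3]
  hp <- as.integer(patch_hw[1]); wp <- as.integer(patch_hw[2])
  if (h %% hp != 0L) stop("height ", h, " not divisible by patch height ", hp)
  if (w %% wp != 0L) stop("width ", w, " not divisible by patch width ", wp)
  gh <- h %/% hp; gw <- w %/% wp
  out <- array(0, c(gh * gw, ch, hp, wp))
  k <- 0L
  for (i in seq_len(gh)) for (j in seq_len(gw)) {
    k <- k + 1L
    out[k, , , ] <- stack[, ((i - 1) * hp + 1):(i * hp),
                          ((j - 1) * wp + 1):(j * wp)]
  }
  out
}

# redundancy-free FFT features of one frame: Np x (10 * Hp * (Wp/2+1))
# matrix of concatenated real/imaginary spectra of the 5 shifted channels.
rfft_patch_features <- function(image, config) {
  stack <- spatial_shift_augment(image, config$shift_px)
  patches <- patch_partition(stack, config$patch_hw)
  np <- dim(patches)[1]
  hp <- config$patch_hw[1]; sw <- config$spec_w
  X <- matrix(0, np, config$patch_feat)
  for (k in seq_len(np)) {
    feats <- array(0, c(10, hp, sw))
    for (ch in 1:5) {
      Fm <- stats::fft(patches[k, ch, , ])[, 1:sw, drop = FALSE]
      feats[ch, , ] <- Re(Fm)
      feats[ch + 5, , ] <- Im(Fm)
    }
    X[k, ] <- as.vector(feats)
  }
  X
}

#' Frequency-domain patch embedding (FF-PE)
#'
#' Shifts, partitions and Fourier-transforms a frame, then layer-normalizes
#' and linearly projects each patch spectrum to a C-wide token, appending the
#' learnable cls token as the last row.
#'
#' @param image H x W matrix matching `config$input_hw`.
#' @param params parameter environment.
#' @param config an [ffvit_config()].
#' @return `(Np + 1) x C` token matrix; attribute `grid_hw` carries the patch
#'   grid shape of the first Np rows.
#' @export
fft_patch_embed <- function(image, params, config) {
  X <- rfft_patch_features(image, config)
  tokens <- ffpe_fwd(X, params, config)$out
  attr(tokens, "grid_hw") <- config$grid_hw
  tokens
}

ffpe_fwd <- function(X, P, config) {
  n1 <- ln_fwd(X, P[["ffpe.ln_g"]], P[["ffpe.ln_b"]])
  l1 <- lin_fwd(n1$out, P[["ffpe.W"]], P[["ffpe.b"]])
  tokens <- rbind(l1$out, P[["ffpe.cls"]])
  list(out = tokens, cache = list(n1 = n1, l1 = l1))
}

ffpe_bwd <- function(dtok, cache, P, acc) {
  np <- nrow(dtok) - 1L
  acc_add(acc, "ffpe.cls", dtok[np + 1L, ])
  dX <- lin_bwd(dtok[seq_len(np), , drop = FALSE], cache$l1, P[["ffpe.W"]],
                acc, "ffpe.W", "ffpe.b")
  ln_bwd(dX, cache$n1, P[["ffpe.ln_g"]], acc, "ffpe.ln_g", "ffpe.ln_b")
  invisible(NULL)
}

# pool a blur map with the latent-compression footprint: width-3 mean along
# rows (w -> w-2), then mean of adjacent row pairs (h -> h/2)
pool_blur_map <- function(map) {
  v <- map$values
  h <- nrow(v); w <- ncol(v)
  pooled <- (v[, 1:(w - 2), drop = FALSE] + v[, 2:(w - 1), drop = FALSE] +
               v[, 3:w, drop = FALSE]) / 3
  out <- (pooled[seq(1, h, by = 2), , drop = FALSE] +
            pooled[seq(2, h, by = 2), , drop = FALSE]) / 2
  structure(list(values = out, grid_hw = dim(out)), class = "blur_map")
}

# Per-frame fixed (parameter-free) features: spectral patch features plus the
# embedded blur-map keys for every pyramid scale. These depend only on the
# image and can be precomputed once per frame.
frame_features <- function(image, config) {
  if (nrow(image) != config$input_hw[1] || ncol(image) != config$input_hw[2])
    stop("expected input of size ",
         paste(config$input_hw, collapse = "x"), ", got ",
         paste(dim(image), collapse = "x"))
  X <- rfft_patch_features(image, config)
  bm <- compute_blur_map(image, config$grid_hw)
  me <- vector("list", config$n_scales)
  cur <- bm
  for (s in seq_len(config$n_scales)) {
    me[[s]] <- unclass(embed_blur_map(cur, config$dim, config$quant_levels))
    if (s < config$n_scales) cur <- pool_blur_map(cur)
  }
  list(X = X, blur_map = bm, me = me)
}

# Full forward pass from precomputed features. Returns the 2*n_scales
# predictions (ordered theta_patch, theta_cls per scale) and, when
# keep_cache, everything needed for the backward pass.
ffvit_fwd <- function(feats, P, config, keep_cache = FALSE) {
  emb <- ffpe_fwd(feats$X, P, config)
  Tk <- emb$out
  Tk <- sweep(Tk, 2, P[["vp"]], "+")
  blk_caches <- vector("list", config$depth)
  for (i in seq_len(config$depth)) {
    r <- attn_block_fwd(Tk, P, paste0("blk", i), config$heads, TRUE)
    Tk <- r$out
    if (keep_cache) blk_caches[[i]] <- r$cache
  }
  grid <- config$grid_hw
  preds <- numeric(2 * config$n_scales)
  sc_caches <- vector("list", config$n_scales)
  for (s in seq_len(config$n_scales)) {
    pre <- paste0("sc", s)
    rb <- attn_block_fwd(Tk, P, paste0(pre, ".bma"), config$heads, FALSE,
                         kv = feats$me[[s]])
    Tb <- rb$out
    n <- nrow(Tb)
    cls <- Tb[n, , drop = FALSE]
    patch <- Tb[-n, , drop = FALSE]
    lc <- NULL
    if (s <= config$lc_layers) {
      lc <- lc_fwd(patch, grid, P, paste0(pre, ".lc"))
      patch <- lc$out
      grid <- lc$grid
    }
    Tk <- rbind(patch, cls)
    sa_caches <- vector("list", config$sa_per_scale)
    for (j in seq_len(config$sa_per_scale)) {
      r <- attn_block_fwd(Tk, P, paste0(pre, ".sa", j), config$heads, TRUE)
      Tk <- r$out
      if (keep_cache) sa_caches[[j]] <- r$cache
    }
    n2 <- nrow(Tk)
    pooled <- colMeans(Tk[-n2, , drop = FALSE])
    hp <- head_fwd(pooled, P, paste0(pre, ".hp"))
    hc <- head_fwd(Tk[n2, ], P, paste0(pre, ".hc"))
    preds[2 * s - 1] <- hp$out
    preds[2 * s] <- hc$out
    if (keep_cache)
      sc_caches[[s]] <- list(bma = rb$cache, lc = lc, sa = sa_caches,
                             hp = hp$cache, hc = hc$cache,
                             n_in = n, n_out = n2, grid_in = if (is.null(lc))
                               grid else c(lc$cache$h, lc$cache$w))
  }
  list(preds = preds,
       cache = if (keep_cache) list(emb = emb$cache, blks = blk_caches,
                                    scales = sc_caches) else NULL)
}

# Backward pass accumulating parameter gradients into `acc`.
# dpreds: gradient of the loss w.r.t. the 2*n_scales predictions.
ffvit_bwd <- function(dpreds, fwd, feats, P, config, acc) {
  cache <- fwd$cache
  dT <- NULL
  for (s in rev(seq_len(config$n_scales))) {
    pre <- paste0("sc", s)
    sc <- cache$scales[[s]]
    n2 <- sc$n_out
    if (is.null(dT)) dT <- matrix(0, n2, config$dim)
    dpooled <- head_bwd(dpreds[2 * s - 1], sc$hp, P, paste0(pre, ".hp"), acc)
    dcls_h <- head_bwd(dpreds[2 * s], sc$hc, P, paste0(pre, ".hc"), acc)
    dT[-n2, ] <- sweep(dT[-n2, , drop = FALSE], 2,
                       dpooled / (n2 - 1), "+")
    dT[n2, ] <- dT[n2, ] + dcls_h
    for (j in rev(seq_len(config$sa_per_scale)))
      dT <- attn_block_bwd(dT, sc$sa[[j]], P, paste0(pre, ".sa", j), acc)
    dcls <- dT[nrow(dT), , drop = FALSE]
    dpatch <- dT[-nrow(dT), , drop = FALSE]
    if (!is.null(sc$lc))
      dpatch <- lc_bwd(dpatch, sc$lc$cache, P, paste0(pre, ".lc"), acc)
    dTb <- rbind(dpatch, dcls)
    dT <- attn_block_bwd(dTb, sc$bma, P, paste0(pre, ".bma"), acc)
  }
  for (i in rev(seq_len(config$depth)))
    dT <- attn_block_bwd(dT, cache$blks[[i]], P, paste0("blk", i), acc)
  acc_add(acc, "vp", colSums(dT))
  ffpe_bwd(dT, cache$emb, P, acc)
  invisible(NULL)
}

#' Multi-scale prediction for one frame
#'
#' Runs the full pipeline (blur map + embedding, FF-PE, backbone transformer,
#' pyramid regressor) on a single frame and returns the per-scale angle
#' predictions. Deterministic: repeated calls give identical results.
#'
#' @param image H x W matrix matching the configured input size.
#' @param params parameter environment from [ffvit_init()] or a fit.
#' @param config the matching [ffvit_config()].
#' @return list with `per_scale` (n_scales x 2 matrix, columns
#'   `theta_patch`, `theta_cls`), `final` (the last scale's cls prediction,
#'   degrees) and `preds` (the flat prediction vector).
#' @export
ffvit_forward <- function(image, params, config) {
  feats <- frame_features(image, config)
  out <- ffvit_fwd(feats, params, config)
  per_scale <- matrix(out$preds, ncol = 2, byrow = TRUE,
                      dimnames = list(paste0("scale", seq_len(config$n_scales) - 1),
                                      c("theta_patch", "theta_cls")))
  list(per_scale = per_scale, final = out$preds[2 * config$n_scales],
       preds = out$preds)
}

#' Latent-compression shape ladder
#'
#' The sequence of patch-grid shapes traversed by the pyramid regressor for a
#' given number of latent-compression stages, starting from the embedding
#' grid (height halves, width shrinks by 2 per stage).
#'
#' @param grid_hw integer(2) starting grid.
#' @param lc_layers number of compression stages.
#' @return (lc_layers + 1) x 2 matrix of grid shapes.
#' @export
lc_ladder <- function(grid_hw, lc_layers) {
  out <- matrix(0L, lc_layers + 1L, 2L,
                dimnames = list(NULL, c("h", "w")))
  g <- as.integer(grid_hw)
  out[1, ] <- g
  for (i in seq_len(lc_layers)) {
    g <- c(g[1] %/% 2L, g[2] - 2L)
    out[i + 1, ] <- g
  }
  out
}
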