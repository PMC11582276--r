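test_that("spatial shift augmentation produces the 5 expected channels", {
  z <- matrix(0, 6, 8)
  st <- spatial_shift_augment(z, 1L)
  expect_equal(dim(st), c(5L, 6L, 8L))
  expect_true(all(st == 0))
  # single bright pixel tracks the shift directions with zero fill
  img <- matrix(0, 6, 8); img[3, 4] <- 1
  st <- spatial_shift_augment(img, 1L)
  expect_equal(st[1, 3, 4], 1)   # original
  expect_equal(st[2, 2, 4], 1)   # up
  expect_equal(st[3, 4, 4], 1)   # down
  expect_equal(st[4, 3, 3], 1)   # left
  expect_equal(st[5, 3, 5], 1)   # right
  expect_equal(sum(st), 5)
  expect_error(spatial_shift_augment(img, 6L), "smaller")
  expect_error(spatial_shift_augment(img, 0L), ">= 1")
})

test_that("patch partition tiles row-major and inverts exactly", {
  set.seed(1)
  stack <- array(runif(5 * 8 * 12), c(5, 8, 12))
  p <- patch_partition(stack, c(4L, 6L))
  expect_equal(dim(p), c(4L, 5L, 4L, 6L))
  # reassemble
  rec <- array(0, dim(stack))
  k <- 0
  for (i in 1:2) for (j in 1:2) {
    k <- k + 1
    rec[, ((i - 1) * 4 + 1):(i * 4), ((j - 1) * 6 + 1):(j * 6)] <- p[k, , , ]
  }
  expect_identical(rec, stack)
  expect_error(patch_partition(stack, c(3L, 6L)), "divisible")
  # toy count: 64x56 with 32x28 -> 4 patches
  st2 <- array(0, c(5, 64, 56))
  expect_equal(dim(patch_partition(st2, c(32L, 28L)))[1], 4L)
})

test_that("full-size partition yields 128 patches and a 15-wide half spectrum", {
  cfg <- ffvit_config()
  expect_equal(cfg$n_patch, 128L)
  expect_equal(cfg$grid_hw, c(8L, 16L))
  expect_equal(cfg$spec_w, 15L)
})

test_that("patch spectra agree with a naive DFT oracle", {
  cfg <- micro_config()
  set.seed(12)
  img <- matrix(runif(8 * 16), 8, 16)
  X <- ffvit:::rfft_patch_features(img, cfg)
  stack <- spatial_shift_augment(img, 1L)
  patches <- patch_partition(stack, cfg$patch_hw)
  for (k in c(1, 5)) for (ch in c(1, 3)) {
    ref <- naive_rfft(patches[k, ch, , ])
    feats <- array(X[k, ], c(10, cfg$patch_hw[1], cfg$spec_w))
    got <- feats[ch, , ] + 1i * feats[ch + 5, , ]
    expect_lt(max(Mod(got - ref)) / max(Mod(ref)), 1e-5)
  }
})

test_that("frequency-domain embedding emits Np+1 tokens, bias rows for a zero image", {
  cfg <- micro_config()
  P <- ffvit_init(cfg, 1)
  tok <- fft_patch_embed(matrix(0, 8, 16), P, cfg)
  expect_equal(dim(tok), c(cfg$n_patch + 1L, cfg$dim))
  for (k in seq_len(cfg$n_patch))
    expect_equal(unname(tok[k, ]), unname(P[["ffpe.b"]]), tolerance = 1e-12)
  expect_equal(unname(tok[cfg$n_patch + 1L, ]), unname(P[["ffpe.cls"]]))
})

test_that("diagonal masking zeroes self-attention weights on probability rows", {
  cfg <- micro_config()
  P <- ffvit_init(cfg, 3)
  set.seed(4)
  x <- matrix(rnorm(9 * cfg$dim), 9, cfg$dim)
  r <- ffvit:::attn_block_fwd(x, P, "blk1", cfg$heads, mask_diag = TRUE)
  for (h in seq_len(cfg$heads)) {
    A <- r$cache$hcache[[h]]$P
    expect_equal(unname(diag(A)), rep(0, 9))
    expect_equal(unname(rowSums(A)), rep(1, 9), tolerance = 1e-6)
  }
  expect_equal(dim(r$out), dim(x))
})

test_that("attention equals a hand-computed softmax on a 3-token toy", {
  cfg <- ffvit_config(input_hw = c(4L, 4L), patch_hw = c(4L, 4L), dim = 4L,
                      depth = 1L, heads = 1L, mlp_dim = 8L, lc_layers = 0L,
                      sa_per_scale = 1L)
  P <- ffvit_init(cfg, 1)
  C <- 4L
  # unit weights: Q = K = V = tokens, tau = 1
  W <- cbind(diag(C), diag(C), diag(C))
  P[["blk1.Wqkv"]] <- W
  P[["blk1.bqkv"]] <- numeric(3 * C)
  P[["blk1.tau"]] <- 1
  x <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                1, 1, 0, 0), 3, 4, byrow = TRUE)
  r <- ffvit:::attn_block_fwd(x, P, "blk1", 1L, mask_diag = TRUE)
  logits <- x %*% t(x)
  expected <- matrix(0, 3, 3)
  for (i in 1:3) {
    z <- logits[i, ]; z[i] <- -Inf
    expected[i, ] <- exp(z) / sum(exp(z))
  }
  expect_equal(r$cache$hcache[[1]]$P, expected, tolerance = 1e-12)
})

test_that("backbone forward is shape preserving, deterministic, depth-respecting", {
  cfg <- micro_config(depth = 3L)
  expect_equal(cfg$depth, 3L)
  P <- ffvit_init(cfg, 7)
  set.seed(2)
  img <- matrix(runif(8 * 16), 8, 16)
  tok <- fft_patch_embed(img, P, cfg)
  tok <- sweep(tok, 2, P[["vp"]], "+")
  t1 <- tok
  for (i in seq_len(cfg$depth))
    t1 <- ffvit:::attn_block_fwd(t1, P, paste0("blk", i), cfg$heads, TRUE)$out
  expect_equal(dim(t1), dim(tok))
  t2 <- tok
  for (i in seq_len(cfg$depth))
    t2 <- ffvit:::attn_block_fwd(t2, P, paste0("blk", i), cfg$heads, TRUE)$out
  expect_identical(t1, t2)
})

test_that("default architecture matches its stated hyperparameters", {
  cfg <- ffvit_config()
  expect_equal(cfg$dim, 192L)
  expect_equal(cfg$depth, 12L)
  expect_equal(cfg$heads, 3L)
  expect_equal(cfg$mlp_dim, 768L)
  expect_equal(cfg$input_hw, c(256L, 448L))
  expect_equal(cfg$patch_hw, c(32L, 28L))
  expect_error(ffvit_config(input_hw = c(256, 488)), "divisible")
})
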