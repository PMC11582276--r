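brute_force_loss <- function(preds, gt, gamma) {
  n_scales <- length(preds) / 2
  total <- 0
  for (m in 1:2) for (n in 0:(n_scales - 1))
    total <- total + gamma^n * abs(gt - preds[2 * n + m])
  total / (2 * n_scales)
}

test_that("multi-scale L1 loss matches a brute-force oracle and its algebra", {
  set.seed(1)
  for (rep in 1:200) {
    preds <- runif(6, -12, 12); gt <- runif(1, -10, 10); g <- runif(1, 0.2, 1)
    expect_equal(as.numeric(multiscale_l1_loss(preds, gt, g)),
                 brute_force_loss(preds, gt, g), tolerance = 1e-12)
  }
  expect_equal(as.numeric(multiscale_l1_loss(rep(2.5, 6), 2.5)), 0)
  # uniform 1-degree error, gamma .5: (1/6)*2*(1+.5+.25)
  expect_equal(as.numeric(multiscale_l1_loss(rep(3, 6), 2, 0.5)),
               0.5833333, tolerance = 1e-6)
  # the last of three scales carries gamma^2 = 0.25
  base <- as.numeric(multiscale_l1_loss(rep(0, 6), 0))
  bump <- as.numeric(multiscale_l1_loss(c(0, 0, 0, 0, 1, 0), 0))
  expect_equal(bump - base, 0.25 / 6, tolerance = 1e-12)
  # non-negative, linear in a common error scale
  expect_equal(as.numeric(multiscale_l1_loss(rep(4, 6), 0)),
               4 * as.numeric(multiscale_l1_loss(rep(1, 6), 0)))
})

test_that("evaluation metrics match hand arithmetic and a loop oracle", {
  m <- eval_metrics(c(1, -1), c(2, -3))
  expect_equal(m$mae, 1.5)
  expect_equal(m$sigma, 0.5)
  expect_equal(m$acc_dir, 100)
  expect_equal(eval_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(mae = 0, sigma = 0, acc_dir = 100, n_frames = 3L))
  expect_equal(eval_metrics(1, -1)$acc_dir, 0)
  # zero ground truth excluded from the direction denominator
  expect_equal(eval_metrics(c(1, 5), c(0, 5))$acc_dir, 100)
  expect_error(eval_metrics(numeric(0), numeric(0)), "empty")
  expect_error(eval_metrics(1:3, 1:2), "mismatch")
  set.seed(2)
  for (rep in 1:20) {
    p <- rnorm(50); g <- rnorm(50)
    m <- eval_metrics(p, g)
    ae <- numeric(0); acc <- 0; nd <- 0
    for (i in 1:50) {
      ae <- c(ae, abs(p[i] - g[i]))
      if (g[i] != 0) { nd <- nd + 1; acc <- acc + (sign(p[i]) == sign(g[i])) }
    }
    expect_equal(m$mae, mean(ae), tolerance = 1e-12)
    expect_equal(m$sigma, sqrt(mean((ae - mean(ae))^2)), tolerance = 1e-12)
    expect_equal(m$acc_dir, 100 * acc / nd, tolerance = 1e-12)
  }
})

test_that("training on a miniature problem reduces the loss deterministically", {
  cfg <- micro_config()
  sp <- scene_params()
  frames <- lapply(seq(-10, 10, by = 2.5), function(th)
    generate_frame(sp, th, 0, seed = 50 + round(th * 2),
                   input_hw = cfg$input_hw))
  frames <- c(frames, frames)    # 18 frames
  ctrl <- ffvit_control(lr = 5e-3, batch_size = 6L, epochs = 4L, seed = 3L,
                        val_fraction = 0.2)
  fit <- ffvit_fit(frames, cfg, ctrl)
  expect_s3_class(fit, "ffvit")
  h <- fit$history
  expect_equal(nrow(h), 4L)
  expect_lt(h$train_loss[4], h$train_loss[1])
  expect_identical(names(h),
                   c("epoch", "train_loss", "val_mae", "val_sigma",
                     "val_accdir"))
  # seeded end-to-end reproducibility
  fit2 <- ffvit_fit(frames, cfg, ctrl)
  expect_identical(fit$history, fit2$history)
  # defaults echo the adopted recipe
  ctrl_def <- ffvit_control()
  expect_equal(ctrl_def$lr, 1e-4)
  expect_equal(ctrl_def$weight_decay, 0.01)
  expect_equal(ctrl_def$batch_size, 512L)
  expect_equal(ctrl_def$gamma, 0.5)
})

test_that("fit object methods expose predictions, residuals and parameters", {
  cfg <- micro_config()
  sp <- scene_params()
  frames <- lapply(seq(-8, 8, by = 4), function(th)
    generate_frame(sp, th, 0, seed = 80 + th, input_hw = cfg$input_hw))
  fit <- ffvit_fit(frames, cfg,
                   ffvit_control(lr = 1e-3, batch_size = 4L, epochs = 2L,
                                 seed = 1L, val_fraction = 0.25))
  expect_output(print(fit), "FF-ViT")
  expect_equal(length(fitted(fit)), length(fit$val_gt))
  expect_equal(residuals(fit), fit$val_gt - fitted(fit))
  expect_true("ffpe.W" %in% names(coef(fit)))
  p <- predict(fit, frames[1:2])
  expect_equal(length(p), 2L)
  expect_true(all(is.finite(p)))
  ck <- file.path(withr::local_tempdir(), "ck.rds")
  ffvit_save(fit, ck)
  fit3 <- ffvit_load(ck)
  expect_equal(predict(fit3, frames[1:2]), p)
})
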