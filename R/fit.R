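#' Multi-scale L1 training objective
#'
#' Deep-supervision loss over the pyramid predictions: with N scales and
#' decay coefficient gamma,
#' `L = 1/(2N) * sum_m sum_{n=0}^{N-1} gamma^n * |theta_gt - theta^n_m|`
#' where m runs over the patch and cls heads. Coarser scales (larger n)
#' are down-weighted geometrically; with gamma = 0.5 the last of three
#' scales carries weight 0.25.
#'
#' @param preds numeric vector of 2N predictions ordered
#'   `(theta^0_patch, theta^0_cls, theta^1_patch, ...)`, or the list returned
#'   by [ffvit_forward()].
#' @param theta_gt ground-truth angle in degrees.
#' @param gamma per-scale decay coefficient in (0, 1].
#' @return scalar loss; attribute `grad` holds dL/dpreds.
#' @export
multiscale_l1_loss <- function(preds, theta_gt, gamma = 0.5) {
  if (is.list(preds)) preds <- preds$preds
  if (length(preds) %% 2L != 0L) stop("preds must hold 2 entries per scale")
  n_scales <- length(preds) %/% 2L
  wts <- rep(gamma^(seq_len(n_scales) - 1), each = 2) / (2 * n_scales)
  err <- preds - theta_gt
  loss <- sum(wts * abs(err))
  attr(loss, "grad") <- wts * sign(err)
  loss
}

#' Orientation evaluation metrics
#'
#' Mean absolute error (degrees), the population standard deviation of the
#' per-frame absolute errors, and the rotation-direction accuracy: the
#' percentage of frames whose predicted tilt has the same sign as the ground
#' truth (frames with zero ground-truth tilt are excluded from the direction
#' denominator). Direction accuracy is what determines whether a servoing
#' robot rotates the correct way.
#'
#' @param preds,gts equal-length numeric vectors of predicted and true
#'   angles in degrees.
#' @return list with `mae`, `sigma`, `acc_dir` (percent, `NA` if no frame has
#'   nonzero ground truth) and `n_frames`.
#' @export
eval_metrics <- function(preds, gts) {
  if (length(preds) == 0 || length(gts) == 0) stop("empty input")
  if (length(preds) != length(gts)) stop("preds/gts length mismatch")
  ae <- abs(preds - gts)
  mae <- mean(ae)
  sigma <- sqrt(mean((ae - mae)^2))
  nz <- gts != 0
  acc <- if (any(nz)) 100 * mean(sign(preds[nz]) == sign(gts[nz])) else NA_real_
  list(mae = mae, sigma = sigma, acc_dir = acc, n_frames = length(preds))
}

# decoupled-weight-decay Adam step over the flat parameter environment;
# decay applies to weight matrices only (not norms, biases, tokens, tau).
# Gradients are clipped to a global L2 norm first: transformer training at
# small batch sizes occasionally produces exploding steps that otherwise
# throw the model into the constant-prediction attractor of the L1 loss.
adamw_step <- function(P, acc, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip_norm = Inf) {
  if (is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(ls(acc), function(nm) sum(acc[[nm]]^2), numeric(1))))
    if (gn > clip_norm)
      for (nm in ls(acc)) acc[[nm]] <- acc[[nm]] * (clip_norm / gn)
  }
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in ls(acc)) {
    g <- acc[[nm]]
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m; state$v[[nm]] <- v
    upd <- (m / b1t) / (sqrt(v / b2t) + eps)
    if (grepl("\\.(W|Wqkv|Wq|Wkv|Wo|W1|W2|Wc)$", nm))
      upd <- upd + wd * P[[nm]]
    P[[nm]] <- P[[nm]] - lr * upd
  }
  invisible(NULL)
}

new_adamw_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  e
}

resolve_frames <- function(data, config) {
  if (is.data.frame(data)) {
    frames <- lapply(seq_len(nrow(data)), function(i) {
      px <- png::readPNG(data$path[i])
      if (length(dim(px)) == 3) px <- px[, , 1]
      structure(list(pixels = px, theta_x = data$theta_x[i],
                     theta_y = data$theta_y[i],
                     frame_id = data$frame_id[i]), class = "pcle_frame")
    })
  } else frames <- data
  stopifnot(all(vapply(frames, inherits, logical(1), "pcle_frame")))
  frames
}

frame_angle <- function(fr) if (fr$theta_x != 0 || fr$theta_y == 0)
  fr$theta_x else fr$theta_y

#' Fit the FF-ViT orientation regressor
#'
#' Trains the frequency-domain vision transformer on labelled frames with
#' AdamW under the multi-scale L1 objective. Per-frame spectral features and
#' blur-map embeddings are parameter-free and precomputed once. A fraction of
#' the data is held out for per-epoch validation (MAE, error spread,
#' direction accuracy); the parameters with the best validation MAE are
#' retained.
#'
#' @param data either a manifest `data.frame` (columns
#'   `path, theta_x, theta_y`, as written by [generate_dataset()]) or a list
#'   of `pcle_frame` objects. The supervised angle of a frame is its nonzero
#'   tilt component (`theta_x` when both are zero).
#' @param config an [ffvit_config()].
#' @param control an [ffvit_control()].
#' @param val_data optional explicit validation set (same forms as `data`);
#'   overrides `control$val_fraction`.
#' @param verbose print per-epoch progress.
#' @return an object of class `ffvit`: list with `params`, `config`,
#'   `control`, `history` (per-epoch data.frame
#'   `epoch, train_loss, val_mae, val_sigma, val_accdir`), validation
#'   predictions of the best epoch (`val_pred`, `val_gt`) and `call`.
#' @seealso [predict.ffvit()], [eval_metrics()]
#' @export
ffvit_fit <- function(data, config = ffvit_config(),
                      control = ffvit_control(), val_data = NULL,
                      verbose = FALSE) {
  cl <- match.call()
  frames <- resolve_frames(data, config)
  with_seed(control$seed, {
    if (is.null(val_data)) {
      n <- length(frames)
      idx_val <- sample(n, max(1L, round(control$val_fraction * n)))
      val_frames <- frames[idx_val]
      frames <- frames[-idx_val]
    } else val_frames <- resolve_frames(val_data, config)

    feats <- lapply(frames, function(fr) frame_features(fr$pixels, config))
    vfeats <- lapply(val_frames, function(fr) frame_features(fr$pixels, config))
    gts <- vapply(frames, frame_angle, numeric(1))
    vgts <- vapply(val_frames, frame_angle, numeric(1))
    if (control$augment == "flip") {
      # left-right mirror with negated angle: an exact symmetry of the
      # lateral blur model
      mfeats <- lapply(frames, function(fr)
        frame_features(fr$pixels[, ncol(fr$pixels):1], config))
    }

    P <- ffvit_init(config, seed = control$seed)
    state <- new_adamw_state()
    nb <- length(frames)
    steps_per_epoch <- length(seq(1, nb, by = control$batch_size))
    warm_steps <- control$warmup_epochs * steps_per_epoch
    step <- 0L
    hist <- list(); best <- list(mae = Inf)
    for (ep in seq_len(control$epochs)) {
      ord <- sample(nb)
      mirror <- if (control$augment == "flip")
        sample(c(TRUE, FALSE), nb, replace = TRUE) else rep(FALSE, nb)
      ep_loss <- 0
      for (start in seq(1, nb, by = control$batch_size)) {
        ids <- ord[start:min(start + control$batch_size - 1, nb)]
        acc <- new.env(parent = emptyenv())
        for (i in ids) {
          f_i <- if (mirror[i]) mfeats[[i]] else feats[[i]]
          g_i <- if (mirror[i]) -gts[i] else gts[i]
          fw <- ffvit_fwd(f_i, P, config, keep_cache = TRUE)
          l <- multiscale_l1_loss(fw$preds, g_i, control$gamma)
          if (!is.finite(l))
            stop("non-finite training loss at epoch ", ep,
                 ", frame ", frames[[i]]$frame_id %||% i)
          ep_loss <- ep_loss + as.numeric(l)
          ffvit_bwd(attr(l, "grad") / length(ids), fw, f_i, P,
                    config, acc)
        }
        step <- step + 1L
        lr_t <- if (warm_steps > 0 && step <= warm_steps)
          control$lr * step / warm_steps else control$lr
        adamw_step(P, acc, state, lr_t, control$weight_decay,
                   clip_norm = control$clip_norm)
      }
      vp <- vapply(vfeats, function(f)
        ffvit_fwd(f, P, config)$preds[2 * config$n_scales], numeric(1))
      vm <- eval_metrics(vp, vgts)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                               val_mae = vm$mae, val_sigma = vm$sigma,
                               val_accdir = vm$acc_dir)
      if (verbose)
        message(sprintf(
          "epoch %2d  loss %.4f  val MAE %.3f  sigma %.3f  acc_dir %.1f%%",
          ep, ep_loss / nb, vm$mae, vm$sigma, vm$acc_dir))
      if (vm$mae < best$mae)
        best <- list(mae = vm$mae, params = as.list(P), epoch = ep,
                     val_pred = vp)
    }
    Pb <- new.env(parent = emptyenv())
    for (nm in names(best$params)) Pb[[nm]] <- best$params[[nm]]
    structure(list(params = Pb, config = config, control = control,
                   history = do.call(rbind, hist),
                   best_epoch = best$epoch,
                   val_pred = best$val_pred, val_gt = vgts,
                   n_train = nb, call = cl),
              class = "ffvit")
  })
}

#' Tenfold cross-validation driver
#'
#' Shuffles the frames, splits them into `k` folds, fits a model on each
#' training complement and evaluates on the held-out fold, reporting per-fold
#' and mean metrics.
#'
#' @param data frames or manifest as in [ffvit_fit()].
#' @param config,control model/training settings.
#' @param k number of folds.
#' @param verbose print per-fold progress.
#' @return list with `folds` (data.frame of per-fold metrics) and `mean`
#'   (averaged metrics).
#' @export
ffvit_xval <- function(data, config = ffvit_config_tiny(),
                       control = ffvit_control(), k = 10L, verbose = FALSE) {
  frames <- resolve_frames(data, config)
  n <- length(frames)
  if (n < k) stop("need at least k frames")
  with_seed(control$seed, {
    fold <- sample(rep(seq_len(k), length.out = n))
    rows <- lapply(seq_len(k), function(f) {
      fit <- ffvit_fit(frames[fold != f], config, control,
                       val_data = frames[fold == f])
      vm <- eval_metrics(fit$val_pred, fit$val_gt)
      if (verbose)
        message(sprintf("fold %d: MAE %.3f acc_dir %.1f", f, vm$mae,
                        vm$acc_dir))
      data.frame(fold = f, mae = vm$mae, sigma = vm$sigma,
                 acc_dir = vm$acc_dir, n = vm$n_frames)
    })
    folds <- do.call(rbind, rows)
    list(folds = folds,
         mean = colMeans(folds[, c("mae", "sigma", "acc_dir")]))
  })
}

#' Save / load a fitted model
#'
#' The checkpoint is a single-file archive of the parameter arrays keyed by
#' module path together with the architecture configuration; the
#' configuration is additionally written next to it as YAML for inspection.
#'
#' @param object an `ffvit` fit (or a bare parameter environment plus
#'   `config`).
#' @param path checkpoint file path (`.rds`).
#' @return `ffvit_load` returns the restored `ffvit` object.
#' @export
ffvit_save <- function(object, path) {
  stopifnot(inherits(object, "ffvit"))
  obj <- object
  obj$params <- as.list(object$params)
  saveRDS(obj, path)
  yaml::write_yaml(unclass(object$config),
                   paste0(sub("\\.rds$", "", path), "_config.yaml"))
  invisible(path)
}

#' @rdname ffvit_save
#' @export
ffvit_load <- function(path) {
  obj <- readRDS(path)
  P <- new.env(parent = emptyenv())
  for (nm in names(obj$params)) P[[nm]] <- obj$params[[nm]]
  obj$params <- P
  class(obj$config) <- "ffvit_config"
  class(obj) <- "ffvit"
  obj
}
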