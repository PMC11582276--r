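# S3 methods for fitted "ffvit" objects.

#' @export
print.ffvit <- function(x, ...) {
  cfg <- x$config
  cat("FF-ViT probe-orientation regressor\n")
  cat(sprintf("  input %dx%d, patch %dx%d (grid %dx%d), width %d, depth %d, %d heads\n",
              cfg$input_hw[1], cfg$input_hw[2], cfg$patch_hw[1],
              cfg$patch_hw[2], cfg$grid_hw[1], cfg$grid_hw[2], cfg$dim,
              cfg$depth, cfg$heads))
  cat(sprintf("  pyramid: %d scales (%d latent compressions), %.2fM parameters\n",
              cfg$n_scales, cfg$lc_layers, ffvit_n_params(x$params) / 1e6))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs on %d frames; best epoch %d\n",
              nrow(x$history), x$n_train, x$best_epoch))
  cat(sprintf("  validation: MAE %.3f deg, sigma %.3f deg, acc_dir %.1f%%\n",
              min(x$history$val_mae), h$val_sigma, h$val_accdir))
  invisible(x)
}

#' @export
summary.ffvit <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE, digits = 4)
  invisible(object$history)
}

#' Extract model parameters
#'
#' @param object an `ffvit` fit.
#' @param ... unused.
#' @return named list of parameter arrays keyed by module path.
#' @export
coef.ffvit <- function(object, ...) as.list(object$params)

#' Predict probe tilt for new frames
#'
#' @param object an `ffvit` fit.
#' @param newdata a `pcle_frame`, a list of them, a manifest `data.frame`, or
#'   a single H x W pixel matrix.
#' @param type `"final"` for the selected (last-scale cls) angle, or
#'   `"all"` for the full multi-scale prediction matrix.
#' @param ... unused.
#' @return numeric vector of angles (degrees), or a list of per-frame
#'   multi-scale predictions when `type = "all"`.
#' @export
predict.ffvit <- function(object, newdata, type = c("final", "all"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata))
    newdata <- list(structure(list(pixels = newdata, theta_x = NA,
                                   theta_y = NA), class = "pcle_frame"))
  if (inherits(newdata, "pcle_frame")) newdata <- list(newdata)
  frames <- resolve_frames(newdata, object$config)
  res <- lapply(frames, function(fr)
    ffvit_forward(fr$pixels, object$params, object$config))
  if (type == "final") vapply(res, `[[`, numeric(1), "final")
  else lapply(res, `[[`, "per_scale")
}

#' @export
fitted.ffvit <- function(object, ...) object$val_pred

#' @export
residuals.ffvit <- function(object, ...) object$val_gt - object$val_pred

#' Training diagnostics plot
#'
#' Draws the training-loss curve and the validation MAE per epoch.
#'
#' @param x an `ffvit` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ffvit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "multi-scale L1", ...)
  graphics::plot(h$epoch, h$val_mae, type = "b", xlab = "epoch",
                 ylab = "validation MAE (deg)", main = "held-out error", ...)
  invisible(h)
}

#' Simulate frames from the generator attached to a fit
#'
#' Draws synthetic frames at uniformly sampled tilts using [generate_frame()]
#' at the model's input size — useful for closed-loop sanity checks of a fit
#' on synthetic data.
#'
#' @param object an `ffvit` fit.
#' @param nsim number of frames.
#' @param seed integer seed.
#' @param params a [scene_params()]; defaults to the generator defaults.
#' @param ... unused.
#' @return list of `pcle_frame` objects.
#' @export
simulate.ffvit <- function(object, nsim = 1, seed = 1L,
                           params = scene_params(), ...) {
  with_seed(seed, {
    th <- stats::runif(nsim, -10, 10)
    lapply(seq_len(nsim), function(i)
      generate_frame(params, th[i], 0, seed = seed + i,
                     input_hw = object$config$input_hw))
  })
}
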