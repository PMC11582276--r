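#' Model configuration
#'
#' Assembles the architecture hyperparameters of the FF-ViT orientation
#' regressor. The defaults are the full-size configuration: 256x448 input,
#' 32x28 patches (an 8x16 patch grid), token width 192, 12 transformer
#' blocks with 3 attention heads, MLP hidden width 768, a 1-px spatial-shift
#' augmentation, and a pyramid angle regressor with two latent-compression
#' stages (three supervised scales).
#'
#' Frames acquired at the native 256x488 sensor size are center-cropped to
#' 256x448 so that the 32x28 patch tiles the image exactly into the 8x16 grid.
#'
#' @param input_hw integer(2), model input height and width in pixels.
#' @param patch_hw integer(2), patch height and width in pixels; must divide
#'   `input_hw` elementwise and the patch width must be even (real-input FFT).
#' @param dim token width C.
#' @param depth number of self-attention blocks in the backbone transformer.
#' @param heads number of attention heads; must divide `dim`.
#' @param mlp_dim hidden width of the per-block MLP (also used by the
#'   regression-head MLPs).
#' @param shift_px pixels shifted by the spatial-shift augmentation.
#' @param lc_layers number of latent-compression stages in the pyramid
#'   regressor; the pyramid has `lc_layers + 1` supervised scales.
#' @param sa_per_scale self-attention blocks applied per pyramid scale after
#'   compression.
#' @param quant_levels discrete quantization levels of the blur value before
#'   sinusoidal embedding.
#' @return an object of class `ffvit_config` (a named list).
#' @examples
#' cfg <- ffvit_config()
#' cfg$grid_hw      # 8 16
#' @export
ffvit_config <- function(input_hw = c(256L, 448L),
                         patch_hw = c(32L, 28L),
                         dim = 192L,
                         depth = 12L,
                         heads = 3L,
                         mlp_dim = 768L,
                         shift_px = 1L,
                         lc_layers = 2L,
                         sa_per_scale = 2L,
                         quant_levels = 100L) {
  input_hw <- as.integer(input_hw); patch_hw <- as.integer(patch_hw)
  if (any(input_hw %% patch_hw != 0L))
    stop("input size ", paste(input_hw, collapse = "x"),
         " is not divisible by patch size ", paste(patch_hw, collapse = "x"))
  if (patch_hw[2] %% 2L != 0L)
    stop("patch width must be even for the redundancy-free FFT")
  if (dim %% heads != 0L)
    stop("token width ", dim, " is not divisible by ", heads, " heads")
  if (lc_layers < 0L) stop("lc_layers must be >= 0")
  grid <- input_hw %/% patch_hw
  cfg <- list(
    input_hw = input_hw, patch_hw = patch_hw,
    grid_hw = grid, n_patch = prod(grid),
    dim = as.integer(dim), depth = as.integer(depth),
    heads = as.integer(heads), head_dim = as.integer(dim %/% heads),
    mlp_dim = as.integer(mlp_dim), shift_px = as.integer(shift_px),
    lc_layers = as.integer(lc_layers),
    n_scales = as.integer(lc_layers + 1L),
    sa_per_scale = as.integer(sa_per_scale),
    quant_levels = as.integer(quant_levels),
    # 5 shifted copies -> 10 channels after Re/Im split; rFFT keeps Wp/2+1 cols
    spec_w = as.integer(patch_hw[2] %/% 2L + 1L)
  )
  cfg$patch_feat <- as.integer(10L * patch_hw[1] * cfg$spec_w)
  class(cfg) <- "ffvit_config"
  cfg
}

#' Reduced configuration for desk-scale experiments
#'
#' A small FF-ViT (64x112 input, 16x14 patches on a 4x8 grid, width 64,
#' 2 blocks, 2 heads, one latent-compression stage) that trains in minutes on
#' one CPU while exercising every architectural component.
#'
#' @param ... overrides passed to [ffvit_config()].
#' @return an `ffvit_config`.
#' @export
ffvit_config_tiny <- function(...) {
  args <- list(input_hw = c(64L, 112L), patch_hw = c(16L, 14L),
               dim = 64L, depth = 2L, heads = 2L, mlp_dim = 256L,
               lc_layers = 1L)
  override <- list(...)
  args[names(override)] <- override
  do.call(ffvit_config, args)
}

#' Training configuration
#'
#' Optimizer and loop settings for [ffvit_fit()]. Defaults follow the adopted
#' training recipe: AdamW with weight decay 0.01 and learning rate 1e-4 at
#' batch size 512, and loss decay coefficient gamma = 0.5 across pyramid
#' scales. Batch size (and with it the learning rate) is meant to be scaled
#' down for desk-scale runs.
#'
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay applied to weight matrices.
#' @param batch_size minibatch size.
#' @param gamma per-scale decay coefficient of the multi-scale L1 loss, in
#'   (0, 1].
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization and shuffling.
#' @param val_fraction fraction of the training set held out for per-epoch
#'   validation when no explicit validation set is given.
#' @param augment `"none"` or `"flip"`: with `"flip"`, each training frame is
#'   presented per epoch either as-is or left-right mirrored with its angle
#'   negated — an exact symmetry of the lateral-blur image model that
#'   doubles texture diversity and anchors the sign decision boundary at 0.
#' @param clip_norm global L2 gradient-norm clip applied per optimizer step
#'   (`Inf` disables).
#' @param warmup_epochs linear learning-rate ramp over this many initial
#'   epochs (0 disables); stabilizes the early steps of the post-norm
#'   transformer at small batch sizes.
#' @return an object of class `ffvit_control` (a named list).
#' @export
ffvit_control <- function(lr = 1e-4, weight_decay = 0.01, batch_size = 512L,
                          gamma = 0.5, epochs = 10L, seed = 1L,
                          val_fraction = 0.15, augment = c("none", "flip"),
                          clip_norm = 1, warmup_epochs = 0) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (lr <= 0) stop("lr must be > 0")
  augment <- match.arg(augment)
  out <- list(lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), gamma = gamma,
              epochs = as.integer(epochs), seed = as.integer(seed),
              val_fraction = val_fraction, augment = augment,
              clip_norm = clip_norm, warmup_epochs = warmup_epochs)
  class(out) <- "ffvit_control"
  out
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
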