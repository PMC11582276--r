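# Two-axis inference through one shared network, and the pivot-point
# kinematics used to act on a predicted rotation.

#' Axis crops for 2-DoF inference
#'
#' The regressor is trained on frames whose left-right blur contrast encodes
#' an x-axis tilt. To infer both axes with one shared network, two crops are
#' taken: `I_x` is a full-width centered horizontal band (preserving the
#' left-right contrast), and `I_y` is a full-height centered vertical band
#' transposed so that its top-bottom contrast maps onto the network's
#' left-right axis. Both are resized (bilinear) to the model input size.
#'
#' @param image H0 x W0 numeric matrix.
#' @param input_hw target model input size.
#' @param band_fraction thickness of each band as a fraction of the source
#'   dimension; below 0.25 a warning is issued.
#' @return list with matrices `I_x` and `I_y`, both `input_hw`.
#' @export
crop_xy <- function(image, input_hw = c(256L, 448L), band_fraction = 0.5) {
  h0 <- nrow(image); w0 <- ncol(image)
  if (band_fraction < 0.25)
    warning("crop band thinner than 25% of the source dimension")
  bh <- max(2L, round(band_fraction * h0))
  bw <- max(2L, round(band_fraction * w0))
  r0 <- floor((h0 - bh) / 2)
  c0 <- floor((w0 - bw) / 2)
  ix <- image[(r0 + 1):(r0 + bh), , drop = FALSE]
  iy <- t(image[, (c0 + 1):(c0 + bw), drop = FALSE])
  resize_to <- function(m, hw)
    as.matrix(EBImage::resize(EBImage::as.Image(m), w = hw[1], h = hw[2]))
  list(I_x = resize_to(ix, input_hw), I_y = resize_to(iy, input_hw))
}

#' Infer both tilt axes from one frame
#'
#' Builds the x/y crops, stacks them as a batch of two, and runs one forward
#' pass of the shared network; the two final (last-scale cls) outputs are the
#' x- and y-axis tilts.
#'
#' @param model an `ffvit` fit (or a list with `params` and `config`).
#' @param image H0 x W0 frame matrix.
#' @param band_fraction passed to [crop_xy()].
#' @return named numeric vector `c(theta_x, theta_y)` in degrees.
#' @export
infer_2dof <- function(model, image, band_fraction = 0.5) {
  crops <- crop_xy(image, model$config$input_hw, band_fraction)
  batch <- list(crops$I_x, crops$I_y)   # 2 x 1 x H x W
  out <- vapply(batch, function(im)
    ffvit_forward(im, model$params, model$config)$final, numeric(1))
  c(theta_x = out[1], theta_y = out[2])
}

#' Pivot-point translation compensation
#'
#' A robot whose pivot is at its base sweeps the probe tip across the tissue
#' when it rotates. Translating the base by
#' `dx = -l sin(theta)`, `dy = l (cos(theta) - 1)` during a rotation `theta`
#' moves the effective pivot to the probe tip at arm length `l`, so the tip
#' stays on the same tissue spot.
#'
#' @param theta rotation angle in degrees.
#' @param l distance from the robot base to the probe tip (mm), > 0.
#' @return named numeric vector `c(dx, dy)` in mm.
#' @examples
#' pivot_translation(90, 10)   # c(-10, -10)
#' @export
pivot_translation <- function(theta, l) {
  if (any(l <= 0)) stop("arm length l must be > 0")
  th <- theta * pi / 180
  c(dx = -l * sin(th), dy = l * (cos(th) - 1))
}
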