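#' Scene parameters for the synthetic pCLE generator
#'
#' The generator renders bright speckle/blob texture (emulating
#' Acriflavin-stained cellular structure seen through a fiber bundle) inside a
#' circular field of view, then applies a spatially varying Gaussian blur whose
#' width grows linearly across the image as a function of the probe tilt, adds
#' sensor noise and clips to \[0, 1\]. A tilt about the x axis makes one
#' lateral half of the frame blurrier than the other; a tilt about the y axis
#' does the same for the top/bottom halves. Sign convention: positive
#' `theta_x` makes the LEFT half blurrier, positive `theta_y` the TOP half.
#'
#' @param fov_radius_fraction circular field-of-view radius as a fraction of
#'   half the smaller image dimension.
#' @param texture_density expected blobs per 1000 px^2.
#' @param base_blur_sigma Gaussian blur sigma (px) at the image center,
#'   i.e. at zero tilt everywhere.
#' @param blur_gain blur sigma gained per degree of tilt at the image border
#'   (px/degree); must be > 0 so the tilt-to-blur-gradient map is injective
#'   in sign.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param angle_step grid step of the tilt sweep in degrees.
#' @param blur_bank number of uniformly spaced blur levels blended per-pixel
#'   to approximate the continuously varying blur (>= 8).
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(fov_radius_fraction = 0.95,
                         texture_density = 8,
                         base_blur_sigma = 1.5,
                         blur_gain = 0.25,
                         noise_sd = 0.01,
                         angle_step = 0.5,
                         blur_bank = 9L) {
  if (blur_gain <= 0) stop("blur_gain must be > 0")
  if (blur_bank < 8L) stop("blur_bank must be >= 8")
  if (angle_step <= 0 || (20 %% angle_step) > 1e-9)
    stop("angle_step must divide the 20-degree angle range")
  out <- list(fov_radius_fraction = fov_radius_fraction,
              texture_density = texture_density,
              base_blur_sigma = base_blur_sigma,
              blur_gain = blur_gain,
              noise_sd = noise_sd,
              angle_step = angle_step,
              blur_bank = as.integer(blur_bank))
  class(out) <- "scene_params"
  out
}

# Gaussian blur that stays valid on images smaller than the FFT brush
# EBImage would build: falls back to a separable edge-replicated convolution
# whenever the truncated kernel does not fit the image.
gauss_blur_safe <- function(m, sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  if (k < min(dim(m)))
    return(as.matrix(EBImage::gblur(m, sigma = sigma)))
  half <- min((min(dim(m)) - 1L) %/% 2L, as.integer(ceiling(3 * sigma)))
  wts <- stats::dnorm(-half:half, sd = sigma)
  wts <- wts / sum(wts)
  pass <- function(x) {   # along rows, edges replicated
    out <- x * 0
    n <- nrow(x)
    for (j in -half:half) {
      rows <- pmin(pmax(seq_len(n) + j, 1L), n)
      out <- out + wts[j + half + 1L] * x[rows, , drop = FALSE]
    }
    out
  }
  t(pass(t(pass(m))))
}

# render the sharp speckle texture inside the circular field of view
render_texture <- function(h, w, params) {
  n_blob <- stats::rpois(1, params$texture_density * h * w / 1000)
  img <- matrix(0, h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  fov_r <- params$fov_radius_fraction * min(h, w) / 2
  if (n_blob > 0) {
    # rejection-free: sample uniformly in the disc
    u <- stats::runif(n_blob); ang <- stats::runif(n_blob, 0, 2 * pi)
    br <- fov_r * sqrt(u)
    bx <- cx + br * cos(ang); by <- cy + br * sin(ang)
    amp <- stats::runif(n_blob, 0.35, 1)
    rad <- stats::runif(n_blob, 0.8, 2.2)
    for (k in seq_len(n_blob)) {
      half <- ceiling(3 * rad[k])
      rr <- max(1, round(by[k]) - half):min(h, round(by[k]) + half)
      cc <- max(1, round(bx[k]) - half):min(w, round(bx[k]) + half)
      d2 <- outer((rr - by[k])^2, (cc - bx[k])^2, "+")
      img[rr, cc] <- img[rr, cc] + amp[k] * exp(-d2 / (2 * rad[k]^2))
    }
  }
  mask <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+") <= fov_r^2
  img <- pmin(img, 1) * mask
  img
}

# per-pixel blur sigma surface for a tilt pair (positive theta_x -> left
# half blurrier, positive theta_y -> top half blurrier)
blur_sigma_field <- function(h, w, theta_x, theta_y, params) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gx <- params$blur_gain * theta_x * (cx - seq_len(w)) / w
  gy <- params$blur_gain * theta_y * (cy - seq_len(h)) / h
  s <- outer(gy, gx, "+") + params$base_blur_sigma
  pmax(s, 0)
}

#' Generate one synthetic pCLE frame
#'
#' Deterministically renders a frame whose spatial blur pattern encodes a
#' known probe tilt (see [scene_params()] for the image model). The
#' continuously varying blur is approximated by blending a bank of uniformly
#' blurred copies of the sharp texture, interpolated per pixel.
#'
#' @param params a [scene_params()] object.
#' @param theta_x,theta_y tilt about the x and y axes in degrees, within
#'   \[-10, 10\].
#' @param seed integer seed; frames are bit-reproducible given
#'   `(params, theta_x, theta_y, seed)`.
#' @param input_hw frame height and width (defaults to the full model input).
#' @param frame_id optional identifier string.
#' @return an object of class `pcle_frame`: list with `pixels` (H x W matrix
#'   in \[0,1\]), `theta_x`, `theta_y`, `seed`, `frame_id`.
#' @examples
#' fr <- generate_frame(scene_params(), 5, 0, seed = 1,
#'                      input_hw = c(64L, 112L))
#' range(fr$pixels)
#' @export
generate_frame <- function(params, theta_x, theta_y, seed,
                           input_hw = c(256L, 448L), frame_id = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (abs(theta_x) > 10 || abs(theta_y) > 10)
    stop("tilt angles must lie within [-10, 10] degrees, got (",
         theta_x, ", ", theta_y, ")")
  h <- as.integer(input_hw[1]); w <- as.integer(input_hw[2])
  with_seed(as.integer(seed), {
    sharp <- render_texture(h, w, params)
    sfield <- blur_sigma_field(h, w, theta_x, theta_y, params)
    smax <- max(sfield)
    levels <- seq(0, max(smax, 1e-6), length.out = params$blur_bank)
    bank <- lapply(levels, function(s) {
      if (s < 1e-3) sharp else gauss_blur_safe(sharp, s)
    })
    # per-pixel linear interpolation between the two bracketing bank levels
    step <- levels[2] - levels[1]
    idx <- pmin(pmax(sfield / step, 0), params$blur_bank - 1)
    lo <- floor(idx); frac <- idx - lo
    img <- matrix(0, h, w)
    for (k in seq_len(params$blur_bank)) {
      wlo <- (lo == k - 1) * (1 - frac)
      whi <- (lo == k - 2) * frac
      wk <- wlo + whi
      if (any(wk > 0)) img <- img + wk * bank[[k]]
    }
    img <- img + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)
    structure(list(pixels = img, theta_x = theta_x, theta_y = theta_y,
                   seed = as.integer(seed),
                   frame_id = frame_id %||%
                     sprintf("fr_x%+05.1f_y%+05.1f_s%d", theta_x, theta_y,
                             as.integer(seed))),
              class = "pcle_frame")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic tilt-sweep dataset on disk
#'
#' Sweeps the tilt grid from -10 to +10 degrees at `params$angle_step`
#' (each requested axis swept independently with the other held at 0),
#' rendering `n_per_angle` frames per grid point, written as 8-bit grayscale
#' PNG plus a CSV manifest. Per-frame seeds are derived deterministically from
#' `seed`, so disjoint base seeds give disjoint train/test frame seeds.
#'
#' @param params a [scene_params()] object.
#' @param n_per_angle frames per angle grid point.
#' @param out_dir output directory (created if missing).
#' @param seed integer base seed.
#' @param axes character vector, subset of `c("x", "y")`: which tilt axes to
#'   sweep.
#' @param input_hw frame size.
#' @return the manifest `data.frame` (columns
#'   `frame_id, path, theta_x, theta_y, seed`), invisibly also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(params, n_per_angle, out_dir, seed,
                             axes = "x", input_hw = c(256L, 448L)) {
  stopifnot(all(axes %in% c("x", "y")), n_per_angle >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  grid <- seq(-10, 10, by = params$angle_step)
  rows <- list(); written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  i <- 0L
  for (axis in axes) for (th in grid) for (rep in seq_len(n_per_angle)) {
    i <- i + 1L
    fseed <- (as.integer(seed) * 10007L + i) %% .Machine$integer.max
    tx <- if (axis == "x") th else 0
    ty <- if (axis == "y") th else 0
    fid <- sprintf("%s_%03d_x%+05.1f_y%+05.1f", axis, rep, tx, ty)
    fr <- generate_frame(params, tx, ty, fseed, input_hw = input_hw,
                         frame_id = fid)
    path <- file.path(out_dir, paste0(fid, ".png"))
    png::writePNG(fr$pixels, path)
    written <- c(written, path)
    rows[[i]] <- data.frame(frame_id = fid, path = path, theta_x = tx,
                            theta_y = ty, seed = fseed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  written <- c(written, mpath)
  ok <- TRUE
  manifest
}

#' Generate an in-memory tilt-sweep dataset
#'
#' Same sweep as [generate_dataset()] without the PNG round trip; used for
#' desk-scale training runs.
#'
#' @inheritParams generate_dataset
#' @return list of `pcle_frame` objects.
#' @export
generate_frames <- function(params, n_per_angle, seed, axes = "x",
                            input_hw = c(256L, 448L)) {
  grid <- seq(-10, 10, by = params$angle_step)
  out <- list(); i <- 0L
  for (axis in axes) for (th in grid) for (rep in seq_len(n_per_angle)) {
    i <- i + 1L
    fseed <- (as.integer(seed) * 10007L + i) %% .Machine$integer.max
    tx <- if (axis == "x") th else 0
    ty <- if (axis == "y") th else 0
    out[[i]] <- generate_frame(params, tx, ty, fseed, input_hw = input_hw)
  }
  out
}
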