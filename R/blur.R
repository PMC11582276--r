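#' No-reference blur score of an image patch
#'
#' Re-blur comparison score in the style of the Crete perceptual blur metric:
#' the patch is re-blurred with a 9-tap uniform averaging kernel along each
#' axis separately, and the loss of neighbor-difference energy is measured.
#' An already-blurry patch loses little difference energy under re-blurring
#' and scores near 1; a sharp patch loses most of it and scores near 0.
#'
#' @param patch numeric matrix, at least 3x3.
#' @return scalar in \[0, 1\]; 0 = sharp, 1 = fully blurred. A patch with no
#'   intensity variation returns 1 (degenerate, maximally blurry by
#'   convention).
#' @examples
#' crete_blur_score(matrix(rep(c(0, 1), 50), 10, 10))
#' @export
crete_blur_score <- function(patch) {
  if (!is.matrix(patch) || nrow(patch) < 3 || ncol(patch) < 3)
    stop("patch must be a matrix of at least 3x3")
  f <- patch
  bv <- blur_1d(f, 9L, along = "rows")     # vertical low-pass
  bh <- blur_1d(f, 9L, along = "cols")     # horizontal low-pass
  dfv <- abs(f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE])
  dfh <- abs(f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE])
  dbv <- abs(bv[-1, , drop = FALSE] - bv[-nrow(f), , drop = FALSE])
  dbh <- abs(bh[, -1, drop = FALSE] - bh[, -ncol(f), drop = FALSE])
  sfv <- sum(dfv); sfh <- sum(dfh)
  if (sfv <= 0 && sfh <= 0) return(1)
  vv <- pmax(0, dfv - dbv); vh <- pmax(0, dfh - dbh)
  blur_v <- if (sfv > 0) (sfv - sum(vv)) / sfv else 1
  blur_h <- if (sfh > 0) (sfh - sum(vh)) / sfh else 1
  min(max(max(blur_v, blur_h), 0), 1)
}

# uniform k-tap moving average along one axis, edge-replicated
blur_1d <- function(m, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(blur_1d(t(m), k, "rows")))
  half <- (k - 1L) %/% 2L
  n <- nrow(m)
  idx <- pmin(pmax(rep(seq_len(n), each = k) +
                     rep(-half:half, times = n), 1L), n)
  # column-wise mean over the k replicated-edge neighbors
  out <- matrix(0, n, ncol(m))
  for (j in -half:half) {
    rows <- pmin(pmax(seq_len(n) + j, 1L), n)
    out <- out + m[rows, , drop = FALSE]
  }
  out / k
}

#' Per-patch blur map of a frame
#'
#' Tiles the image into a `grid_hw` grid of equal non-overlapping tiles and
#' scores each with [crete_blur_score()]. With the model's patch grid this is
#' the blur map M fed to the blur-mapping attention module.
#'
#' @param image numeric H x W matrix.
#' @param grid_hw integer(2): grid height and width (tiles).
#' @return a `blur_map` object: list with `values` (grid_h x grid_w matrix in
#'   \[0,1\]) and `grid_hw`.
#' @export
compute_blur_map <- function(image, grid_hw) {
  grid_hw <- as.integer(grid_hw)
  h <- nrow(image); w <- ncol(image)
  if (h %% grid_hw[1] != 0L)
    stop("image height ", h, " not divisible by grid height ", grid_hw[1])
  if (w %% grid_hw[2] != 0L)
    stop("image width ", w, " not divisible by grid width ", grid_hw[2])
  th <- h %/% grid_hw[1]; tw <- w %/% grid_hw[2]
  vals <- matrix(0, grid_hw[1], grid_hw[2])
  for (i in seq_len(grid_hw[1])) for (j in seq_len(grid_hw[2])) {
    tile <- image[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
    vals[i, j] <- crete_blur_score(tile)
  }
  structure(list(values = vals, grid_hw = grid_hw), class = "blur_map")
}

# sinusoidal absolute positional encoding table: Q positions x C dims
sinusoid_table <- function(q, c_dim) {
  pos <- 0:(q - 1)
  i <- 0:(c_dim / 2 - 1)
  freq <- 1 / 10000^(2 * i / c_dim)
  arg <- outer(pos, freq)
  tab <- matrix(0, q, c_dim)
  tab[, seq(1, c_dim, by = 2)] <- sin(arg)
  tab[, seq(2, c_dim, by = 2)] <- cos(arg)
  tab
}

#' Embed a blur map as tokens
#'
#' Each blur value in \[0,1\] is quantized to one of `quant_levels` discrete
#' indices and replaced by the sinusoidal absolute positional encoding of that
#' index at width `c_dim`; the grid is flattened row-major to `Np` token rows.
#'
#' @param map a [compute_blur_map()] result.
#' @param c_dim even token width C.
#' @param quant_levels number of quantization levels Q.
#' @return `Np x C` numeric matrix (class `embedded_blur_map`).
#' @export
embed_blur_map <- function(map, c_dim, quant_levels = 100L) {
  stopifnot(inherits(map, "blur_map"))
  if (c_dim %% 2L != 0L) stop("c_dim must be even")
  v <- map$values
  if (any(v < 0 | v > 1)) {
    warning("blur values outside [0,1] clipped")
    v <- pmin(pmax(v, 0), 1)
  }
  idx <- round(v * (quant_levels - 1L))
  tab <- sinusoid_table(quant_levels, c_dim)
  # row-major flatten of the grid: grid row i, col j -> token (i-1)*W + j
  flat <- as.vector(t(idx)) + 1L
  tok <- tab[flat, , drop = FALSE]
  class(tok) <- c("embedded_blur_map", class(tok))
  tok
}

#' Classical focus measures
#'
#' Standard no-reference focus/blur measures used for the image distortion
#' study across probe tilts:
#' \describe{
#'   \item{MoI}{intensity moment of inertia about the intensity centroid
#'     (normalized by total intensity and image area); sensitive to how spread
#'     the bright structure is.}
#'   \item{NFBM}{the re-blur comparison score of [crete_blur_score()].}
#'   \item{H-FFT}{fraction of non-DC spectral energy above a radial frequency
#'     threshold (default one quarter of Nyquist).}
#'   \item{LAPV}{variance of the 4-neighbor Laplacian response.}
#'   \item{GEDR}{gradient energy of the image divided by the gradient energy
#'     of a Gaussian re-blurred copy (sigma 1); >= 1, higher = sharper.}
#' }
#' All are invariant to adding a constant intensity offset except MoI, which
#' depends on absolute intensity.
#'
#' @param image numeric matrix.
#' @param name one of `"MoI"`, `"NFBM"`, `"H-FFT"`, `"LAPV"`, `"GEDR"`.
#' @param hfft_threshold radial frequency threshold for `H-FFT` as a fraction
#'   of Nyquist.
#' @return scalar focus value.
#' @export
focus_metric <- function(image, name, hfft_threshold = 0.25) {
  if (length(image) == 0) stop("image must be non-empty")
  valid <- c("MoI", "NFBM", "H-FFT", "LAPV", "GEDR")
  if (!name %in% valid)
    stop("unknown focus metric '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  h <- nrow(image); w <- ncol(image)
  switch(name,
    "MoI" = {
      tot <- sum(image)
      if (tot <= 0) return(0)
      rr <- row(image); cc <- col(image)
      rbar <- sum(rr * image) / tot; cbar <- sum(cc * image) / tot
      sum(image * ((rr - rbar)^2 + (cc - cbar)^2)) / (tot * h * w)
    },
    "NFBM" = crete_blur_score(image),
    "H-FFT" = {
      sp <- stats::fft(image)
      e <- Mod(sp)^2
      e[1, 1] <- 0                       # drop DC
      tote <- sum(e)
      if (tote <= 0) return(0)
      fr <- ifelse(0:(h - 1) <= h / 2, 0:(h - 1), (0:(h - 1)) - h) / h
      fc <- ifelse(0:(w - 1) <= w / 2, 0:(w - 1), (0:(w - 1)) - w) / w
      rad <- sqrt(outer(fr^2, fc^2, "+"))
      sum(e[rad > hfft_threshold * 0.5]) / tote
    },
    "LAPV" = {
      if (h < 3 || w < 3) stop("LAPV needs at least a 3x3 image")
      lap <- image[2:(h - 1), 2:(w - 1)] * -4 +
        image[1:(h - 2), 2:(w - 1)] + image[3:h, 2:(w - 1)] +
        image[2:(h - 1), 1:(w - 2)] + image[2:(h - 1), 3:w]
      mean((lap - mean(lap))^2)
    },
    "GEDR" = {
      b <- gauss_blur_safe(image, 1)
      gE <- function(m) {
        gx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
        gy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
        sum(gx^2) + sum(gy^2)
      }
      den <- gE(b)
      if (den <= 0) return(1)
      gE(image) / den
    })
}

#' Distortion rates across a tilt sweep and the probe working range
#'
#' Given a focus-metric series over strictly increasing tilt angles, the
#' distortion rate of each adjacent angle pair is the absolute difference of
#' their metric values normalized by the series mean magnitude, in percent.
#' The working range is the widest symmetric interval around 0 degrees within
#' which every rate is at most `threshold_factor` times the mean rate outside
#' the interval — the tilt band within which image quality degrades slowly
#' enough for scanning.
#'
#' @param angles strictly increasing numeric vector (degrees), length >= 3.
#' @param values focus-metric values at `angles`.
#' @param threshold_factor inside/outside mean-rate factor defining the
#'   working range.
#' @return list with `rates` (data.frame: `angle_lo`, `angle_hi`, `mid`,
#'   `rate_pct`) and `working_range` (`c(lo, hi)` degrees).
#' @export
distortion_study <- function(angles, values, threshold_factor = 0.5) {
  if (length(angles) < 3) stop("need at least 3 points")
  if (length(values) != length(angles)) stop("angles/values length mismatch")
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  scale <- mean(abs(values))
  d <- abs(diff(values))
  rate <- if (scale > 0) 100 * d / scale else d * 0
  mid <- (angles[-1] + angles[-length(angles)]) / 2
  rates <- data.frame(angle_lo = angles[-length(angles)],
                      angle_hi = angles[-1], mid = mid, rate_pct = rate)
  cand <- sort(unique(abs(mid)))
  best <- NULL
  for (a in cand) {
    inside <- abs(mid) <= a + 1e-12
    if (!any(inside) || all(inside)) next
    if (max(rate[inside]) <= threshold_factor * mean(rate[!inside]) + 1e-12)
      best <- a
  }
  wr <- if (is.null(best)) c(0, 0) else c(-best, best)
  # a fully flat series is undistorted everywhere: full span
  if (all(rate <= 1e-9)) wr <- range(angles)
  list(rates = rates, working_range = wr)
}
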