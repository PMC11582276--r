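# Shared fixtures: configurations small enough for fast tests, a speckle
# image generator, and naive reference implementations used as oracles.

micro_config <- function(...) {
  args <- list(input_hw = c(8L, 16L), patch_hw = c(4L, 4L), dim = 8L,
               depth = 1L, heads = 2L, mlp_dim = 16L, lc_layers = 1L,
               sa_per_scale = 1L)
  override <- list(...)
  args[names(override)] <- override
  do.call(ffvit_config, args)
}

# bright speckle on dark background, reproducible
make_speckle <- function(h = 32, w = 28, seed = 5, density = 0.06) {
  set.seed(seed)
  img <- matrix(0, h, w)
  n <- round(density * h * w)
  idx <- sample(h * w, n)
  img[idx] <- runif(n, 0.5, 1)
  img
}

gauss_blur <- function(img, sigma) as.matrix(EBImage::gblur(img, sigma = sigma))

# naive re-implementation of the re-blur comparison blur score, written as a
# direct double loop from the metric's definition (independent of the
# package's vectorized implementation)
naive_crete <- function(f) {
  h <- nrow(f); w <- ncol(f)
  reblur <- function(m, vertical) {
    out <- m
    for (i in 1:h) for (j in 1:w) {
      acc <- 0
      for (t in -4:4) {
        ii <- if (vertical) min(max(i + t, 1), h) else i
        jj <- if (vertical) j else min(max(j + t, 1), w)
        acc <- acc + m[ii, jj]
      }
      out[i, j] <- acc / 9
    }
    out
  }
  bv <- reblur(f, TRUE); bh <- reblur(f, FALSE)
  dfv <- abs(f[2:h, ] - f[1:(h - 1), ]); dbv <- abs(bv[2:h, ] - bv[1:(h - 1), ])
  dfh <- abs(f[, 2:w] - f[, 1:(w - 1)]); dbh <- abs(bh[, 2:w] - bh[, 1:(w - 1)])
  sfv <- sum(dfv); sfh <- sum(dfh)
  if (sfv <= 0 && sfh <= 0) return(1)
  bl_v <- if (sfv > 0) (sfv - sum(pmax(0, dfv - dbv))) / sfv else 1
  bl_h <- if (sfh > 0) (sfh - sum(pmax(0, dfh - dbh))) / sfh else 1
  min(max(max(bl_v, bl_h), 0), 1)
}

# naive 2D DFT (double sum) keeping the non-redundant half spectrum
naive_rfft <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(complex(real = 0, imaginary = 0), h, w %/% 2 + 1)
  for (u in 0:(h - 1)) for (v in 0:(w %/% 2)) {
    s <- 0 + 0i
    for (r in 0:(h - 1)) for (c in 0:(w - 1))
      s <- s + m[r + 1, c + 1] * exp(-2i * pi * (u * r / h + v * c / w))
    out[u + 1, v + 1] <- s
  }
  out
}

# blur-map half statistics
half_stat_lr <- function(map) {
  w <- ncol(map$values)
  mean(map$values[, 1:(w %/% 2)]) - mean(map$values[, (w - w %/% 2 + 1):w])
}
half_stat_tb <- function(map) {
  h <- nrow(map$values)
  mean(map$values[1:(h %/% 2), ]) - mean(map$values[(h - h %/% 2 + 1):h, ])
}
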