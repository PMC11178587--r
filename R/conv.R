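## Small 2-D convolution helpers shared by the classical filters, the SSIM
## window statistics and the circular-statistics neighbourhood sums.
## Kernels are small (3x3 .. 7x7), so convolution is done by vectorised
## shift-and-add rather than FFT.

pad2 <- function(x, p, mode = c("replicate", "reflect", "zero")) {
  mode <- match.arg(mode)
  h <- nrow(x); w <- ncol(x)
  ri <- switch(mode,
    replicate = c(rep(1L, p), seq_len(h), rep(h, p)),
    reflect   = c(rev(seq_len(p) + 1L), seq_len(h), h - seq_len(p)),
    zero      = NULL)
  if (mode == "zero") {
    out <- matrix(0, h + 2L * p, w + 2L * p)
    out[p + seq_len(h), p + seq_len(w)] <- x
    return(out)
  }
  ci <- switch(mode,
    replicate = c(rep(1L, p), seq_len(w), rep(w, p)),
    reflect   = c(rev(seq_len(p) + 1L), seq_len(w), w - seq_len(p)))
  x[ri, ci, drop = FALSE]
}

## "Same"-size 2-D correlation with an odd square kernel.
conv2same <- function(x, k, mode = "replicate") {
  ks <- nrow(k)
  stopifnot(ks == ncol(k), ks %% 2L == 1L)
  p <- (ks - 1L) %/% 2L
  xp <- pad2(x, p, mode)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (di in seq_len(ks)) for (dj in seq_len(ks)) {
    if (k[di, dj] == 0) next
    out <- out + k[di, dj] * xp[di:(di + h - 1L), dj:(dj + w - 1L)]
  }
  out
}

## Sum over the w x w neighbourhood (zero padding), used for windowed
## counts and circular resultants.
boxsum <- function(x, wsize) {
  conv2same(x, matrix(1, wsize, wsize), mode = "zero")
}

gaussian_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g / sum(g)
}
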