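## Minimal neural-network engine for the polarimetric denoising diffusion
## network: 3x3 convolutions (im2col on BLAS matmul), group normalisation,
## SiLU, average pooling / nearest upsampling, single-head self-attention,
## sinusoidal time embeddings and dense layers, each with a hand-written
## backward pass. Activations are stored as (B*H*W) x C matrices with rows
## ordered pixel-column-major within each image; `sd = c(h, w, b)` tracks
## the spatial shape alongside.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu_f <- function(x) {
  s <- sigmoid(x)
  list(y = x * s, cache = list(x = x, s = s))
}
silu_b <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

## Neighbour index table for k x k convolution with zero padding.
## Returns (b*h*w) x k^2 matrix of source rows; out-of-bounds entries point
## to the sentinel row b*h*w + 1 (an all-zero row appended before gather).
conv_index <- function(h, w, b, k) {
  r <- (k - 1L) %/% 2L
  hw <- h * w
  ii <- rep(seq_len(h), times = w)
  jj <- rep(seq_len(w), each = h)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  idx1 <- matrix(0L, hw, k * k)
  for (o in seq_len(nrow(offs))) {
    si <- ii + offs$di[o]; sj <- jj + offs$dj[o]
    ok <- si >= 1L & si <= h & sj >= 1L & sj <= w
    v <- si + (sj - 1L) * h
    v[!ok] <- NA_integer_
    idx1[, o] <- v
  }
  out <- matrix(0L, b * hw, k * k)
  for (bb in seq_len(b)) {
    blk <- idx1 + (bb - 1L) * hw
    blk[is.na(idx1)] <- b * hw + 1L
    out[(bb - 1L) * hw + seq_len(hw), ] <- blk
  }
  out
}

conv_f <- function(x, W, bias, idx) {
  n <- nrow(x); cin <- ncol(x); k2 <- ncol(idx)
  xz <- rbind(x, 0)
  cols <- matrix(0, n, k2 * cin)
  for (o in seq_len(k2)) {
    cols[, (o - 1L) * cin + seq_len(cin)] <- xz[idx[, o], , drop = FALSE]
  }
  y <- cols %*% W
  y <- sweep(y, 2L, bias, `+`)
  list(y = y, cache = list(cols = cols, idx = idx, W = W, cin = cin, n = n))
}

conv_b <- function(dy, cache) {
  W <- cache$W; idx <- cache$idx; cin <- cache$cin; n <- cache$n
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- tcrossprod(dy, W)      # dy %*% t(W)
  dx <- matrix(0, n, cin)
  for (o in seq_len(ncol(idx))) {
    tgt <- idx[, o]
    m <- tgt <= n
    blk <- dcols[, (o - 1L) * cin + seq_len(cin), drop = FALSE]
    dx[tgt[m], ] <- dx[tgt[m], , drop = FALSE] + blk[m, , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

## Group normalisation over (pixels x channels-in-group) per image.
gn_groups <- function(C, groups = 8L) {
  g <- groups
  while (C %% g != 0L) g <- g %/% 2L
  max(g, 1L)
}

gn_f <- function(x, gamma, beta, image_id, B, groups, eps = 1e-5) {
  C <- ncol(x)
  g <- gn_groups(C, groups)
  cg <- C %/% g
  grp <- rep(seq_len(g), each = cg)          # group of each channel
  npix <- nrow(x) / B
  s1 <- rowsum(x, image_id)                  # B x C sums
  s2 <- rowsum(x * x, image_id)
  agg <- function(m) {                       # B x C -> B x g sums
    out <- matrix(0, B, g)
    for (gg in seq_len(g)) out[, gg] <- rowSums(m[, grp == gg, drop = FALSE])
    out
  }
  nels <- npix * cg
  mu <- agg(s1) / nels                       # B x g
  var <- agg(s2) / nels - mu^2
  sdv <- sqrt(pmax(var, 0) + eps)
  mu_bc <- mu[, grp, drop = FALSE]           # B x C
  sd_bc <- sdv[, grp, drop = FALSE]
  xhat <- (x - mu_bc[image_id, , drop = FALSE]) / sd_bc[image_id, , drop = FALSE]
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, cache = list(xhat = xhat, sd_bc = sd_bc, image_id = image_id,
                           gamma = gamma, grp = grp, B = B, nels = nels))
}

gn_b <- function(dy, cache) {
  xhat <- cache$xhat; grp <- cache$grp; B <- cache$B
  id <- cache$image_id; nels <- cache$nels
  g <- max(grp)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, `*`)
  s_d <- rowsum(dxhat, id)                   # B x C
  s_dx <- rowsum(dxhat * xhat, id)
  agg <- function(m) {
    out <- matrix(0, B, g)
    for (gg in seq_len(g)) out[, gg] <- rowSums(m[, grp == gg, drop = FALSE])
    out
  }
  m_d <- (agg(s_d) / nels)[, grp, drop = FALSE]    # B x C group means
  m_dx <- (agg(s_dx) / nels)[, grp, drop = FALSE]
  dx <- (dxhat - m_d[id, , drop = FALSE] -
           xhat * m_dx[id, , drop = FALSE]) / cache$sd_bc[id, , drop = FALSE]
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dense_f <- function(x, W, bias) {
  y <- sweep(x %*% W, 2L, bias, `+`)
  list(y = y, cache = list(x = x, W = W))
}
dense_b <- function(dy, cache) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

## 2x2 average pooling index sets: four (coarse-row -> fine-row) maps.
pool_index <- function(h, w, b) {
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  hc <- h %/% 2L; wc <- w %/% 2L
  hw <- h * w; hwc <- hc * wc
  ic <- rep(seq_len(hc), times = wc)
  jc <- rep(seq_len(wc), each = hc)
  base <- list()
  kk <- 1L
  for (dj in 0:1) for (di in 0:1) {
    fi <- 2L * ic - 1L + di; fj <- 2L * jc - 1L + dj
    base[[kk]] <- fi + (fj - 1L) * h
    kk <- kk + 1L
  }
  lapply(base, function(v) {
    as.vector(outer(v, (seq_len(b) - 1L) * hw, `+`))
  })
}

pool_f <- function(x, pidx) {
  y <- (x[pidx[[1]], , drop = FALSE] + x[pidx[[2]], , drop = FALSE] +
        x[pidx[[3]], , drop = FALSE] + x[pidx[[4]], , drop = FALSE]) / 4
  list(y = y, cache = list(pidx = pidx, n = nrow(x)))
}
pool_b <- function(dy, cache) {
  dx <- matrix(0, cache$n, ncol(dy))
  for (k in 1:4) dx[cache$pidx[[k]], ] <- dy / 4
  dx
}

up_f <- function(x, pidx, nfine) {
  y <- matrix(0, nfine, ncol(x))
  for (k in 1:4) y[pidx[[k]], ] <- x
  list(y = y, cache = list(pidx = pidx))
}
up_b <- function(dy, cache) {
  p <- cache$pidx
  dy[p[[1]], , drop = FALSE] + dy[p[[2]], , drop = FALSE] +
    dy[p[[3]], , drop = FALSE] + dy[p[[4]], , drop = FALSE]
}

## Single-head self-attention over spatial positions, one image at a time.
attn_f <- function(x, Wq, Wk, Wv, Wo, B) {
  C <- ncol(x); npix <- nrow(x) / B
  y <- matrix(0, nrow(x), C)
  per <- vector("list", B)
  sc <- 1 / sqrt(C)
  for (bb in seq_len(B)) {
    rows <- (bb - 1L) * npix + seq_len(npix)
    xb <- x[rows, , drop = FALSE]
    Q <- xb %*% Wq; K <- xb %*% Wk; V <- xb %*% Wv
    S <- tcrossprod(Q, K) * sc
    S <- S - max(S)                 # global-max stabiliser (post-GN inputs)
    A <- exp(S); A <- A / rowSums(A)
    Yb <- A %*% V
    y[rows, ] <- Yb %*% Wo
    per[[bb]] <- list(xb = xb, Q = Q, K = K, V = V, A = A, Yb = Yb)
  }
  list(y = y, cache = list(per = per, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                           B = B, npix = npix, sc = sc))
}

attn_b <- function(dy, cache) {
  B <- cache$B; npix <- cache$npix; sc <- cache$sc
  C <- ncol(dy)
  dx <- matrix(0, nrow(dy), C)
  dWq <- dWk <- dWv <- dWo <- matrix(0, C, C)
  for (bb in seq_len(B)) {
    rows <- (bb - 1L) * npix + seq_len(npix)
    cb <- cache$per[[bb]]
    dyb <- dy[rows, , drop = FALSE]
    dWo <- dWo + crossprod(cb$Yb, dyb)
    dYb <- tcrossprod(dyb, cache$Wo)         # dyb %*% t(Wo)
    dA <- tcrossprod(dYb, cb$V)              # dYb %*% t(V)
    dV <- crossprod(cb$A, dYb)
    dS <- cb$A * (dA - rowSums(dA * cb$A))
    dQ <- (dS %*% cb$K) * sc
    dK <- (crossprod(dS, cb$Q)) * sc
    dWq <- dWq + crossprod(cb$xb, dQ)
    dWk <- dWk + crossprod(cb$xb, dK)
    dWv <- dWv + crossprod(cb$xb, dV)
    dx[rows, ] <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) +
      dV %*% t(cache$Wv)
  }
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

## Sinusoidal embedding of integer time-points (B x dim).
time_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

## Adam optimiser step over parallel named lists of params and grads.
adam_step <- function(pars, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pars)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    pars[[nm]] <- pars[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(pars = pars, state = state)
}

adam_init <- function(pars) {
  list(t = 0L,
       m = lapply(pars, function(p) p * 0),
       v = lapply(pars, function(p) p * 0))
}
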