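## The epsilon-prediction U-Net of the polarimetric denoising diffusion
## network. The architecture follows the standard diffusion U-Net design:
## an encoder-decoder with wide residual blocks (group norm -> SiLU ->
## 3x3 conv, twice, with a learned per-block time-embedding bias), 2x2
## average pooling / nearest upsampling between resolution levels, skip
## concatenation between mirrored levels, self-attention at the coarsest
## resolutions, and a zero-initialised output convolution. Channel widths
## are `width * mults`; `mults = c(1, 2, 4, 8)` is the full-scale
## configuration, smaller presets are used for desk-scale experiments.
##
## The network is expressed as a flat list of ops executed by a stack
## machine; the backward pass walks the same list in reverse, so forward
## and gradient code cannot drift apart.

build_unet_ops <- function(in_ch, width, mults, attn_levels) {
  L <- length(mults)
  ch <- width * mults
  ops <- list()
  add <- function(...) ops[[length(ops) + 1L]] <<- list(...)
  res_id <- 0L
  resblock <- function(cin, cout, attn) {
    res_id <<- res_id + 1L
    p <- sprintf("res%d", res_id)
    add(kind = "push")
    add(kind = "gn", name = paste0(p, ".gn1"), C = cin)
    add(kind = "silu")
    add(kind = "conv", name = paste0(p, ".conv1"), k = 3L, cin = cin, cout = cout)
    add(kind = "tbias", name = paste0(p, ".temb"), cout = cout)
    add(kind = "gn", name = paste0(p, ".gn2"), C = cout)
    add(kind = "silu")
    add(kind = "conv", name = paste0(p, ".conv2"), k = 3L, cin = cout, cout = cout)
    if (cin == cout) add(kind = "pop_add")
    else add(kind = "pop_add_conv", name = paste0(p, ".short"), cin = cin,
             cout = cout)
    if (attn) {
      add(kind = "push")
      add(kind = "gn", name = paste0(p, ".agn"), C = cout)
      add(kind = "attn", name = paste0(p, ".attn"), C = cout)
      add(kind = "pop_add")
    }
  }
  add(kind = "conv", name = "stem", k = 3L, cin = in_ch, cout = ch[1])
  for (l in seq_len(L)) {
    cin <- if (l == 1L) ch[1] else ch[l - 1L]
    if (l > 1L) add(kind = "pool")
    resblock(cin, ch[l], attn = l %in% attn_levels)
    if (l < L) add(kind = "push_skip")
  }
  resblock(ch[L], ch[L], attn = L %in% attn_levels)
  for (l in rev(seq_len(L - 1L))) {
    add(kind = "up")
    add(kind = "pop_concat")  # concat skip of level l (ch[l] channels)
    resblock(ch[l] + ch[l + 1L], ch[l], attn = l %in% attn_levels)
  }
  add(kind = "gn", name = "head.gn", C = ch[1])
  add(kind = "silu")
  add(kind = "conv", name = "head.conv", k = 3L, cin = ch[1], cout = in_ch,
      zero_init = TRUE)
  ops
}

init_unet_params <- function(ops, temb_dim, groups) {
  pars <- list()
  for (op in ops) {
    if (op$kind == "conv" || op$kind == "pop_add_conv") {
      k2 <- if (op$kind == "conv") op$k^2 else 1L
      fan <- k2 * op$cin
      sdv <- if (isTRUE(op$zero_init)) 0 else sqrt(2 / fan)
      pars[[paste0(op$name, ".W")]] <-
        matrix(stats::rnorm(fan * op$cout, 0, sdv), fan, op$cout)
      pars[[paste0(op$name, ".b")]] <- numeric(op$cout)
    } else if (op$kind == "gn") {
      pars[[paste0(op$name, ".gamma")]] <- rep(1, op$C)
      pars[[paste0(op$name, ".beta")]] <- numeric(op$C)
    } else if (op$kind == "tbias") {
      pars[[paste0(op$name, ".W")]] <-
        matrix(stats::rnorm(temb_dim * op$cout, 0, sqrt(1 / temb_dim)),
               temb_dim, op$cout)
      pars[[paste0(op$name, ".b")]] <- numeric(op$cout)
    } else if (op$kind == "attn") {
      for (wnm in c("Wq", "Wk", "Wv", "Wo")) {
        sdv <- if (wnm == "Wo") 0 else sqrt(1 / op$C)
        pars[[paste0(op$name, ".", wnm)]] <-
          matrix(stats::rnorm(op$C^2, 0, sdv), op$C, op$C)
      }
    }
  }
  ## shared time-embedding MLP: sinusoid(temb_dim) -> dense -> SiLU -> dense
  pars[["tmlp.W1"]] <- matrix(stats::rnorm(temb_dim^2, 0, sqrt(1 / temb_dim)),
                              temb_dim, temb_dim)
  pars[["tmlp.b1"]] <- numeric(temb_dim)
  pars[["tmlp.W2"]] <- matrix(stats::rnorm(temb_dim^2, 0, sqrt(1 / temb_dim)),
                              temb_dim, temb_dim)
  pars[["tmlp.b2"]] <- numeric(temb_dim)
  pars
}

#' Initialise an untrained PDDN denoiser model
#'
#' @param in_ch input/output channels (16 polarisation states).
#' @param width base channel width.
#' @param mults channel multipliers per resolution level (coarsening by 2x
#'   per level); `c(1, 2, 4, 8)` is the full-scale configuration.
#' @param attn_levels resolution levels (1 = finest) carrying a
#'   self-attention block; defaults to the two coarsest.
#' @param groups target number of group-normalisation groups.
#' @param temb_dim dimension of the time embedding.
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `pddn_model` (untrained).
#' @export
pddn_model <- function(in_ch = 16L, width = 8L, mults = c(1L, 2L, 4L),
                       attn_levels = NULL, groups = 8L,
                       temb_dim = 4L * width, seed = 1L) {
  L <- length(mults)
  if (is.null(attn_levels)) attn_levels <- if (L >= 2L) c(L - 1L, L) else L
  ops <- build_unet_ops(in_ch, width, mults, attn_levels)
  pars <- with_seed(seed, init_unet_params(ops, temb_dim, groups))
  structure(list(ops = ops, pars = pars,
                 config = list(in_ch = in_ch, width = width, mults = mults,
                               attn_levels = attn_levels, groups = groups,
                               temb_dim = temb_dim, levels = L, seed = seed),
                 manifest = NULL),
            class = "pddn_model")
}

## (h, w, C, B) array -> (B*h*w) x C activation matrix.
img_to_rows <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
}
rows_to_img <- function(m, h, w, b) {
  aperm(array(m, c(h, w, b, ncol(m))), c(1L, 2L, 4L, 3L))
}

## Execute the op list. Returns prediction and (optionally) the tape of
## caches for the backward pass.
unet_forward <- function(model, x, t, want_grad = FALSE) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; B <- d[4]
  stopifnot(d[3] == model$config$in_ch)
  lv <- model$config$levels
  if (h %% 2^(lv - 1L) != 0L || w %% 2^(lv - 1L) != 0L) {
    stop("patch size must be divisible by ", 2^(lv - 1L))
  }
  pars <- model$pars
  groups <- model$config$groups

  ## shared time-embedding MLP
  te0 <- time_embedding(t, model$config$temb_dim)
  td1 <- dense_f(te0, pars[["tmlp.W1"]], pars[["tmlp.b1"]])
  ts1 <- silu_f(td1$y)
  td2 <- dense_f(ts1$y, pars[["tmlp.W2"]], pars[["tmlp.b2"]])
  temb <- td2$y

  ## spatial index caches per level
  cidx <- list(); pidx <- list()
  hh <- h; ww <- w
  for (l in seq_len(lv)) {
    cidx[[l]] <- conv_index(hh, ww, B, 3L)
    if (l < lv) pidx[[l]] <- pool_index(hh, ww, B)
    hh <- hh %/% 2L; ww <- ww %/% 2L
  }

  X <- img_to_rows(x)
  level <- 1L
  npix_at <- function(l) (h %/% 2^(l - 1L)) * (w %/% 2^(l - 1L)) * B
  image_id_at <- function(l) rep(seq_len(B), each = npix_at(l) %/% B)
  stack <- list()
  tape <- if (want_grad) vector("list", length(model$ops)) else NULL

  for (oi in seq_along(model$ops)) {
    op <- model$ops[[oi]]
    kind <- op$kind
    if (kind == "conv") {
      r <- conv_f(X, pars[[paste0(op$name, ".W")]],
                  pars[[paste0(op$name, ".b")]], cidx[[level]])
      if (want_grad) tape[[oi]] <- r$cache
      X <- r$y
    } else if (kind == "gn") {
      r <- gn_f(X, pars[[paste0(op$name, ".gamma")]],
                pars[[paste0(op$name, ".beta")]],
                image_id_at(level), B, groups)
      if (want_grad) tape[[oi]] <- r$cache
      X <- r$y
    } else if (kind == "silu") {
      r <- silu_f(X)
      if (want_grad) tape[[oi]] <- r$cache
      X <- r$y
    } else if (kind == "tbias") {
      r <- dense_f(temb, pars[[paste0(op$name, ".W")]],
                   pars[[paste0(op$name, ".b")]])
      X <- X + r$y[image_id_at(level), , drop = FALSE]
      if (want_grad) tape[[oi]] <- list(dcache = r$cache, level = level)
    } else if (kind == "pool") {
      r <- pool_f(X, pidx[[level]])
      if (want_grad) tape[[oi]] <- r$cache
      X <- r$y
      level <- level + 1L
    } else if (kind == "up") {
      level <- level - 1L
      r <- up_f(X, pidx[[level]], npix_at(level))
      if (want_grad) tape[[oi]] <- r$cache
      X <- r$y
    } else if (kind == "push" || kind == "push_skip") {
      stack[[length(stack) + 1L]] <- X
    } else if (kind == "pop_add") {
      S <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      X <- X + S
    } else if (kind == "pop_add_conv") {
      S <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- conv_f(S, pars[[paste0(op$name, ".W")]],
                  pars[[paste0(op$name, ".b")]],
                  matrix(seq_len(nrow(S)), nrow(S), 1L))
      if (want_grad) tape[[oi]] <- r$cache
      X <- X + r$y
    } else if (kind == "pop_concat") {
      S <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (want_grad) tape[[oi]] <- list(nskip = ncol(S))
      X <- cbind(S, X)
    } else if (kind == "attn") {
      r <- attn_f(X, pars[[paste0(op$name, ".Wq")]],
                  pars[[paste0(op$name, ".Wk")]],
                  pars[[paste0(op$name, ".Wv")]],
                  pars[[paste0(op$name, ".Wo")]], B)
      if (want_grad) tape[[oi]] <- r$cache
      X <- X + r$y
    } else stop("unknown op ", kind)
  }

  eps_hat <- rows_to_img(X, h, w, B)
  if (!want_grad) return(list(eps_hat = eps_hat))
  list(eps_hat = eps_hat, X = X, tape = tape,
       tcaches = list(td1 = td1$cache, ts1 = ts1$cache, td2 = td2$cache),
       dims = c(h = h, w = w, B = B))
}

## Backward pass: walks the op list in reverse, returns named gradients.
unet_backward <- function(model, fwd, deps) {
  grads <- list()
  addg <- function(nm, g) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  }
  h <- fwd$dims[["h"]]; w <- fwd$dims[["w"]]; B <- fwd$dims[["B"]]
  dX <- img_to_rows(deps)
  dtemb <- NULL
  gstack <- list()
  for (oi in rev(seq_along(model$ops))) {
    op <- model$ops[[oi]]
    kind <- op$kind
    cc <- fwd$tape[[oi]]
    if (kind == "conv") {
      r <- conv_b(dX, cc)
      addg(paste0(op$name, ".W"), r$dW)
      addg(paste0(op$name, ".b"), r$db)
      dX <- r$dx
    } else if (kind == "gn") {
      r <- gn_b(dX, cc)
      addg(paste0(op$name, ".gamma"), r$dgamma)
      addg(paste0(op$name, ".beta"), r$dbeta)
      dX <- r$dx
    } else if (kind == "silu") {
      dX <- silu_b(dX, cc)
    } else if (kind == "tbias") {
      db_img <- rowsum(dX, rep(seq_len(B), each = nrow(dX) %/% B))
      r <- dense_b(db_img, cc$dcache)
      addg(paste0(op$name, ".W"), r$dW)
      addg(paste0(op$name, ".b"), r$db)
      dtemb <- if (is.null(dtemb)) r$dx else dtemb + r$dx
      ## dX passes through unchanged
    } else if (kind == "pool") {
      dX <- pool_b(dX, cc)
    } else if (kind == "up") {
      dX <- up_b(dX, cc)
    } else if (kind == "push" || kind == "push_skip") {
      g <- gstack[[length(gstack)]]; gstack[[length(gstack)]] <- NULL
      dX <- dX + g
    } else if (kind == "pop_add") {
      gstack[[length(gstack) + 1L]] <- dX
    } else if (kind == "pop_add_conv") {
      r <- conv_b(dX, cc)
      addg(paste0(op$name, ".W"), r$dW)
      addg(paste0(op$name, ".b"), r$db)
      gstack[[length(gstack) + 1L]] <- r$dx
    } else if (kind == "pop_concat") {
      ns <- cc$nskip
      gstack[[length(gstack) + 1L]] <- dX[, seq_len(ns), drop = FALSE]
      dX <- dX[, -seq_len(ns), drop = FALSE]
    } else if (kind == "attn") {
      r <- attn_b(dX, cc)
      for (wnm in c("Wq", "Wk", "Wv", "Wo")) {
        addg(paste0(op$name, ".", wnm), r[[paste0("d", wnm)]])
      }
      dX <- dX + r$dx
    }
  }
  ## back through the shared time-embedding MLP
  if (!is.null(dtemb)) {
    r2 <- dense_b(dtemb, fwd$tcaches$td2)
    addg("tmlp.W2", r2$dW); addg("tmlp.b2", r2$db)
    ds <- silu_b(r2$dx, fwd$tcaches$ts1)
    r1 <- dense_b(ds, fwd$tcaches$td1)
    addg("tmlp.W1", r1$dW); addg("tmlp.b1", r1$db)
  }
  grads
}

#' Predict the diffusion noise for a batch of patches
#'
#' Applies the epsilon-prediction U-Net to patches `x` at time-points `t`.
#'
#' @param model a [pddn_model()].
#' @param x array (h, w, 16, B) or a single (h, w, 16) patch, values in
#'   \[-1, 1\].
#' @param t integer time-point(s), length 1 or B.
#' @return predicted noise with the shape of `x`.
#' @export
pddn_predict <- function(model, x, t) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  B <- dim(x)[4]
  if (length(t) == 1L) t <- rep(t, B)
  out <- unet_forward(model, x, t, want_grad = FALSE)$eps_hat
  if (single) dim(out) <- dim(out)[1:3]
  out
}
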