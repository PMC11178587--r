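## Self-supervised training of the polarimetric denoising diffusion
## network: sample a clean patch x0, a time-point t and Gaussian noise
## eps, corrupt with the closed-form q_sample, and regress eps with an
## L1 loss (Adam optimiser). Trained on high-quality (multi-shot
## averaged) intensities only; no paired low-quality data is needed.

#' Named training presets
#'
#' `"paper"` is the full-scale configuration (T = 1000 time-points,
#' 128 x 128 x 16 patches, width 64 with multipliers 1,2,4,8,
#' self-attention at the two coarsest levels, batch 32, learning rate
#' 1e-4, 100k steps). `"desk"` is a small configuration sized for
#' single-CPU experiments and tests (T = 200, 32 x 32 patches, width 12
#' with multipliers 1,2,4, self-attention at the coarsest level, batch 4,
#' 2500 steps).
#'
#' @param name `"paper"` or `"desk"`.
#' @return named list of training/configuration values.
#' @export
pddn_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(T = 1000L, beta_start = 1e-4, beta_end = 0.02,
         width = 64L, mults = c(1L, 2L, 4L, 8L), attn_levels = c(3L, 4L),
         patch = 128L, batch = 32L, steps = 100000L, lr = 1e-4)
  } else {
    list(T = 200L, beta_start = 1e-4, beta_end = 0.02,
         width = 12L, mults = c(1L, 2L, 4L), attn_levels = 3L,
         patch = 32L, batch = 4L, steps = 2500L, lr = 1e-3)
  }
}

## Random augmented crop: rotation by multiples of 90 degrees, flips, and
## random cropping with mirror padding when the frame is smaller than the
## requested patch.
augment_crop <- function(frame, mask, patch) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (h < patch || w < patch) {
    pr <- max(0L, patch - h); pc <- max(0L, patch - w)
    ri <- c(seq_len(h), rev(seq_len(min(pr, h))))
    ci <- c(seq_len(w), rev(seq_len(min(pc, w))))
    frame <- frame[ri, ci, , drop = FALSE]
    mask <- mask[ri, ci, drop = FALSE]
    h <- dim(frame)[1]; w <- dim(frame)[2]
  }
  i0 <- sample.int(h - patch + 1L, 1L) - 1L
  j0 <- sample.int(w - patch + 1L, 1L) - 1L
  x <- frame[i0 + seq_len(patch), j0 + seq_len(patch), , drop = FALSE]
  m <- mask[i0 + seq_len(patch), j0 + seq_len(patch), drop = FALSE]
  if (stats::runif(1) < 0.5) { x <- x[patch:1, , , drop = FALSE]; m <- m[patch:1, , drop = FALSE] }
  if (stats::runif(1) < 0.5) { x <- x[, patch:1, , drop = FALSE]; m <- m[, patch:1, drop = FALSE] }
  k <- sample.int(4L, 1L) - 1L
  if (k > 0L) for (r in seq_len(k)) {
    x <- aperm(x, c(2L, 1L, 3L))[patch:1, , , drop = FALSE]
    m <- t(m)[patch:1, , drop = FALSE]
  }
  list(x = x, mask = m)
}

#' Train the polarimetric denoising diffusion network
#'
#' Self-supervised epsilon-prediction training on high-quality intensity
#' frames. Per step: draw a batch of augmented patches, a uniform
#' time-point and standard-normal noise, corrupt with [q_sample()], and
#' minimise the L1 distance between the network output and the drawn
#' noise. Reflection-masked pixels are excluded from the loss.
#'
#' @param hq_frames list of H x W x 16 arrays already rescaled to \[-1, 1\]
#'   (see [rescale_unit()]), or [intensity_tensor()]s.
#' @param config list as from [pddn_preset()]; fields `T`, `beta_start`,
#'   `beta_end`, `width`, `mults`, `patch`, `batch`, `steps`, `lr`.
#' @param masks optional list of H x W logical matrices marking
#'   supra-threshold reflections to exclude (TRUE = excluded).
#' @param seed seed controlling initialisation, patch sampling and noise;
#'   fixed seed gives a bit-identical manifest and loss curve.
#' @param bounds intensity bounds used for the \[-1, 1\] rescale, stored in
#'   the manifest so inference can reproduce the normalisation.
#' @param verbose print running loss every `log_every` steps.
#' @param log_every loss-curve resolution in steps.
#' @param lr_decay cosine-decay the learning rate to `lr / 10` over the
#'   run (standard practice; disable with `FALSE` for short smoke runs).
#' @param ema_decay exponential-moving-average decay for the weights used
#'   at inference (0 disables EMA).
#' @return a trained `pddn_model` whose `manifest` records the config,
#'   schedule, seed, loss curve and normalisation bounds.
#' @export
train_pddn <- function(hq_frames, config = pddn_preset("desk"), masks = NULL,
                       seed = 1L, bounds = NULL, verbose = FALSE,
                       log_every = 50L, lr_decay = TRUE, ema_decay = 0.999) {
  if (length(hq_frames) == 0L) stop("empty training set")
  frames <- lapply(hq_frames, unclass)
  if (is.null(masks)) {
    masks <- lapply(frames, function(f) matrix(FALSE, dim(f)[1], dim(f)[2]))
  }
  sched <- make_schedule(config$T, config$beta_start, config$beta_end)
  model <- pddn_model(in_ch = 16L, width = config$width,
                      mults = config$mults,
                      attn_levels = config$attn_levels,
                      seed = child_seed(seed, 11))
  opt <- adam_init(model$pars)
  ema <- if (ema_decay > 0) model$pars else NULL
  loss_curve <- numeric(0)
  running <- NA_real_

  with_seed(child_seed(seed, 12), {
    for (step in seq_len(config$steps)) {
      B <- config$batch; P <- config$patch
      x0 <- array(0, c(P, P, 16L, B))
      wmask <- array(1, c(P, P, 16L, B))
      for (b in seq_len(B)) {
        fi <- sample.int(length(frames), 1L)
        cr <- augment_crop(frames[[fi]], masks[[fi]], P)
        x0[, , , b] <- cr$x
        wmask[, , , b] <- array(rep(!cr$mask, 16L), c(P, P, 16L))
      }
      t <- sample.int(sched$T, B, replace = TRUE)
      eps <- array(stats::rnorm(length(x0)), dim(x0))
      ab <- sched$alpha_bar[t]
      xt <- x0
      for (b in seq_len(B)) {
        xt[, , , b] <- sqrt(ab[b]) * x0[, , , b] + sqrt(1 - ab[b]) * eps[, , , b]
      }
      fwd <- unet_forward(model, xt, t, want_grad = TRUE)
      resid <- fwd$eps_hat - eps
      wsum <- sum(wmask)
      loss <- sum(abs(resid) * wmask) / wsum
      if (!is.finite(loss)) {
        stop("non-finite training loss at step ", step,
             " (lr = ", config$lr, ", running loss = ", running, ")")
      }
      dl <- sign(resid) * wmask / wsum
      grads <- unet_backward(model, fwd, dl)
      lr_t <- if (isTRUE(lr_decay)) {
        config$lr * (0.1 + 0.45 * (1 + cos(pi * step / config$steps)))
      } else config$lr
      upd <- adam_step(model$pars, grads, opt, lr_t)
      model$pars <- upd$pars; opt <- upd$state
      if (!is.null(ema)) {
        dk <- min(ema_decay, (step + 1) / (step + 10))  # warm-up ramp
        for (nm in names(ema)) {
          ema[[nm]] <- dk * ema[[nm]] + (1 - dk) * model$pars[[nm]]
        }
      }
      running <- if (is.na(running)) loss else 0.95 * running + 0.05 * loss
      if (step %% log_every == 0L || step == config$steps) {
        loss_curve <- c(loss_curve, running)
        if (verbose) message(sprintf("step %d  L1 %.5f", step, running))
      }
    }
  })

  if (!is.null(ema)) model$pars <- ema
  model$manifest <- list(
    config = config, seed = seed, loss = "L1", optimiser = "adam",
    schedule = list(T = sched$T, beta_start = sched$beta_start,
                    beta_end = sched$beta_end),
    bounds = bounds, loss_curve = loss_curve,
    final_loss = running, steps = config$steps)
  model$sched <- sched
  model
}
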