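## Single-pass diffusion denoising of polarimetric intensity frames,
## plus the deterministic baseline filters (median, Gaussian blur,
## gradient anisotropic diffusion) and reflection masking.

#' Linear rescale of intensities to \[-1, 1\] and back
#'
#' @param x numeric array.
#' @param bounds list with `min` and `max` (recorded so the mapping is
#'   invertible); computed from `x` when omitted.
#' @return `rescale_unit`: list with `x` (rescaled array) and `bounds`;
#'   `unrescale_unit`: array on the original intensity scale.
#' @export
rescale_unit <- function(x, bounds = NULL) {
  if (is.null(bounds)) bounds <- list(min = min(x), max = max(x))
  if (bounds$max <= bounds$min) stop("degenerate intensity bounds")
  list(x = 2 * (x - bounds$min) / (bounds$max - bounds$min) - 1,
       bounds = bounds)
}

#' @rdname rescale_unit
#' @export
unrescale_unit <- function(x, bounds) {
  (x + 1) / 2 * (bounds$max - bounds$min) + bounds$min
}

#' Robust noise estimate of an image channel
#'
#' Immerkaer's fast noise-variance estimator: the image is convolved with
#' a Laplacian-difference mask that annihilates locally planar structure,
#' and sigma is recovered from the mean absolute response.
#'
#' @param x numeric matrix (one channel).
#' @return estimated Gaussian noise standard deviation.
#' @export
estimate_sigma <- function(x) {
  L <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  r <- conv2same(x, L, mode = "replicate")
  sqrt(pi / 2) / 6 * mean(abs(r))
}

#' Pick the diffusion time-point matching an observed noise level
#'
#' Treats a noisy frame as a forward-diffusion state: chooses the t whose
#' marginal noise scale `sqrt(1 - alpha_bar_t)` is closest to the
#' estimated noise sigma (in \[-1, 1\] units).
#'
#' @param sigma noise standard deviation in rescaled units.
#' @param sched a [make_schedule()] object.
#' @return integer time-point in 1..T.
#' @export
select_tstar <- function(sigma, sched) {
  max(1L, which.min(abs(sqrt(1 - sched$alpha_bar) - sigma)))
}

#' Single-pass diffusion denoising of a patch
#'
#' Treats the noisy input (in \[-1, 1\] units) as the diffusion state at
#' time-point `t_star` and applies one reverse posterior-mean step in
#' x0-form: the network predicts the noise, [x0_from_eps()] inverts the
#' closed-form corruption, and the result is clipped to \[-1, 1\]. No noise
#' is injected (terminal step).
#'
#' @param x_noisy (h, w, 16) array in \[-1, 1\].
#' @param model a trained [pddn_model()].
#' @param sched a [make_schedule()] object.
#' @param t_star time-point the input is assumed to sit at (default 1;
#'   see [select_tstar()] for noise-matched selection).
#' @return denoised (h, w, 16) array in \[-1, 1\].
#' @export
denoise_single_pass <- function(x_noisy, model, sched, t_star = 1L) {
  if (t_star < 1L || t_star > sched$T) stop("t_star outside [1, T]")
  eps_hat <- pddn_predict(model, x_noisy, t_star)
  x0_from_eps(x_noisy, t_star, eps_hat, sched, clip = TRUE)
}

## Cosine blending window for overlapped tiling (strictly positive so the
## normalising weight sum never vanishes at frame borders).
cosine_window <- function(n) {
  w <- 0.05 + 0.95 * sin(pi * (seq_len(n) - 0.5) / n)^2
  w
}

#' Denoise a full intensity frame by overlapped tiling
#'
#' Splits the frame into overlapping tiles of the model's training patch
#' size, denoises each with [denoise_single_pass()], and blends tiles with
#' a cosine window. Operates on the intensity scale: the frame is rescaled
#' to \[-1, 1\] using the model's recorded training bounds (or its own range
#' when the model carries none) and mapped back afterwards.
#'
#' @param I an [intensity_tensor()] or H x W x 16 array.
#' @param model trained [pddn_model()] with a manifest.
#' @param sched schedule; defaults to the one stored in the model.
#' @param t_star time-point; `"auto"` picks it per frame by matching the
#'   estimated noise level ([estimate_sigma()], [select_tstar()]).
#' @param tile tile size (default: training patch size).
#' @param overlap tile overlap in pixels (default: half a tile).
#' @return denoised [intensity_tensor()].
#' @export
denoise_frame <- function(I, model, sched = NULL, t_star = "auto",
                          tile = NULL, overlap = NULL) {
  if (is.null(sched)) sched <- model$sched
  if (is.null(sched)) stop("no schedule: pass sched or use a trained model")
  x <- unclass(I)
  h <- dim(x)[1]; w <- dim(x)[2]
  bounds <- model$manifest$bounds
  rs <- rescale_unit(x, bounds)
  xs <- rs$x
  if (is.null(tile)) tile <- model$manifest$config$patch
  if (is.null(tile)) tile <- min(h, w)
  tile <- min(tile, h, w)
  div <- 2^(model$config$levels - 1L)
  tile <- max(div, (tile %/% div) * div)
  if (is.null(overlap)) overlap <- tile %/% 2L
  stride <- max(1L, tile - overlap)

  if (identical(t_star, "auto")) {
    sig <- mean(apply(xs, 3, estimate_sigma))
    t_star <- select_tstar(sig, sched)
  }

  starts <- function(total) {
    s <- seq(1L, max(1L, total - tile + 1L), by = stride)
    if (s[length(s)] + tile - 1L < total) s <- c(s, total - tile + 1L)
    s
  }
  wv <- cosine_window(tile)
  wt <- wv %o% wv
  acc <- array(0, dim(xs))
  wgt <- matrix(0, h, w)
  for (i0 in starts(h)) for (j0 in starts(w)) {
    ri <- i0 + seq_len(tile) - 1L; ci <- j0 + seq_len(tile) - 1L
    patch <- xs[ri, ci, , drop = FALSE]
    den <- denoise_single_pass(patch, model, sched, t_star)
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] +
      den * array(rep(wt, 16L), c(tile, tile, 16L))
    wgt[ri, ci] <- wgt[ri, ci] + wt
  }
  out <- acc / array(rep(wgt, 16L), dim(acc))
  intensity_tensor(unrescale_unit(out, rs$bounds),
                   shots = attr(I, "shots") %||% 1L,
                   meta = c(attr(I, "meta"),
                            list(denoised = "pddn", t_star = t_star)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Vectorised median of 9 values given as a n x 9 matrix: a fixed
## compare-exchange sorting network evaluated with pmin/pmax, so the
## median costs O(n) vector operations rather than a per-pixel sort.
median9 <- function(m) {
  x <- lapply(1:9, function(i) m[, i])
  ex <- function(i, j) {
    lo <- pmin(x[[i]], x[[j]]); hi <- pmax(x[[i]], x[[j]])
    x[[i]] <<- lo; x[[j]] <<- hi
  }
  for (pass in 1:8) for (k in seq_len(9 - pass)) ex(k, k + 1)
  x[[5]]
}

medf3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  xp <- pad2(x, 1L, "replicate")
  m <- matrix(0, h * w, 9L)
  k <- 1L
  for (dj in 0:2) for (di in 0:2) {
    m[, k] <- as.vector(xp[di + seq_len(h), dj + seq_len(w)])
    k <- k + 1L
  }
  matrix(median9(m), h, w)
}

## Perona-Malik gradient anisotropic diffusion (exponential conductance).
grad_aniso <- function(x, iterations = 5L, conductance = 1, time_step = 0.125) {
  h <- nrow(x); w <- ncol(x)
  for (it in seq_len(iterations)) {
    xn <- x[c(1L, seq_len(h - 1L)), ] - x
    xs <- x[c(seq_len(h - 1L) + 1L, h), ] - x
    xw <- x[, c(1L, seq_len(w - 1L))] - x
    xe <- x[, c(seq_len(w - 1L) + 1L, w)] - x
    g <- function(d) exp(-(d / conductance)^2)
    x <- x + time_step * (g(xn) * xn + g(xs) * xs + g(xw) * xw + g(xe) * xe)
  }
  x
}

#' Deterministic baseline denoising filters
#'
#' Applied channel-wise over the 16 polarisation states:
#' `MEDF` = 3 x 3 median filter, `GBLR` = normalised 5 x 5 Gaussian kernel
#' (DC gain 1), `GRAD` = Perona-Malik gradient anisotropic diffusion
#' (5 iterations, conductance 1).
#'
#' @param x H x W x 16 array or [intensity_tensor()] (also accepts a
#'   single H x W matrix).
#' @param method one of `"MEDF"`, `"GBLR"`, `"GRAD"`.
#' @param params optional list overriding defaults: `gblr_sigma` (1.0),
#'   `grad_iterations` (5), `grad_conductance` (1), `grad_time_step`
#'   (0.125).
#' @return filtered array of the same shape (and class, for intensity
#'   tensors).
#' @export
baseline_filter <- function(x, method = c("MEDF", "GBLR", "GRAD"),
                            params = list()) {
  method <- match.arg(method)
  p <- utils::modifyList(list(gblr_sigma = 1.0, grad_iterations = 5L,
                              grad_conductance = 1, grad_time_step = 0.125),
                         params)
  one <- function(ch) {
    switch(method,
      MEDF = medf3(ch),
      GBLR = conv2same(ch, gaussian_kernel(5L, p$gblr_sigma), "replicate"),
      GRAD = grad_aniso(ch, p$grad_iterations, p$grad_conductance,
                        p$grad_time_step))
  }
  if (is.matrix(x)) return(one(x))
  out <- unclass(x)
  for (k in seq_len(dim(out)[3])) out[, , k] <- one(out[, , k])
  if (inherits(x, "intensity_tensor")) {
    intensity_tensor(out, shots = attr(x, "shots"), meta = attr(x, "meta"))
  } else out
}

#' Mask supra-threshold intensity reflections
#'
#' Flags pixels whose maximum over the 16 channels exceeds a threshold
#' (specular reflections saturate all states), then dilates the mask.
#' Masked pixels are excluded from training losses and evaluation to
#' avoid spurious artefacts.
#'
#' @param x H x W x 16 array or [intensity_tensor()].
#' @param threshold absolute intensity threshold, or a quantile in (0, 1]
#'   when `quantile = TRUE`.
#' @param quantile interpret `threshold` as a quantile of the per-pixel
#'   channel maxima.
#' @param dilate dilation radius in pixels (chessboard metric).
#' @return H x W logical matrix, TRUE = masked.
#' @export
mask_reflections <- function(x, threshold, quantile = FALSE, dilate = 1L) {
  mx <- apply(unclass(x), c(1, 2), max)
  thr <- if (quantile) stats::quantile(mx, threshold, names = FALSE) else threshold
  m <- mx > thr
  if (dilate > 0L && any(m)) {
    m <- boxsum(m * 1, 2L * dilate + 1L) > 0
  }
  m
}
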