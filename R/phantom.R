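## Synthetic brain-tissue phantom.
##
## Emulates the study's acquisition setting: a tissue-class map (grey and
## white matter, a lesion with centre and infiltration ring, background),
## a smooth fibre-orientation field disrupted inside the lesion, per-pixel
## ground-truth Mueller matrices composed as depolariser x retarder x
## diattenuator, forward imaging through calibration matrices G/A,
## pseudo-Gaussian shot noise, and n-shot averaging (n = 1 low quality,
## n = 8 high quality, n = 16 super-high quality).

## Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a per-stage child seed from a top-level seed (stays < 2^31).
child_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

## Separable Gaussian smoothing with replicate borders.
gauss_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  sm1 <- function(m) {  # smooth along rows (first dim)
    h <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(h), (-r):r, `+`), 1L), h)
    out <- matrix(0, h, ncol(m))
    for (d in seq_along(k)) out <- out + k[d] * m[idx[, d], , drop = FALSE]
    out
  }
  t(sm1(t(sm1(x))))
}

#' Tissue-class labels of the synthetic phantom
#'
#' Named integer codes used in the phantom's `class_map`.
#' @export
PHANTOM_CLASSES <- c(background = 0L, grey_matter = 1L, white_matter = 2L,
                     tumour_centre = 3L, tumour_infiltration = 4L)

#' Specification of a synthetic polarimetric phantom
#'
#' Defines the geometry, per-tissue-class optical parameters, noise model
#' and seed of a synthetic acquisition. Defaults reproduce the study
#' conditions: a 512 x 384 camera frame, tissue classes with white matter
#' showing the strongest retardance and most coherent fibre orientation, a
#' lesion whose centre has uniformly random fibre azimuth, and
#' pseudo-Gaussian acquisition noise (a zero-mean Gaussian scale mixture:
#' symmetric and bell-shaped but slightly heavier-tailed than normal).
#'
#' @param h,w frame size in pixels (camera default 512 x 384).
#' @param optics named list per class of `delta` (retardance, degrees),
#'   `diag` (depolariser diagonal, each in (0, 1]), `d` (diattenuation
#'   magnitude, < 1).
#' @param sigma acquisition noise standard deviation of the Gaussian core,
#'   in intensity units (M11-normalised intensities are O(1)).
#' @param kappa contamination fraction of the noise mixture in [0, 1);
#'   `kappa = 0` gives pure Gaussian noise.
#' @param wmult contamination width multiplier (> 1).
#' @param n_shots number of single-shot acquisitions to simulate.
#' @param smooth_frac spatial correlation length of the class blobs as a
#'   fraction of the frame height.
#' @param orient_frac correlation length of the fibre-orientation flow.
#' @param gm_disp,ti_disp angular dispersion (degrees) added to the smooth
#'   orientation field in grey matter / tumour infiltration as a
#'   spatially correlated perturbation (correlation length
#'   `jitter_frac * h`); the tumour centre is uniformly random per pixel
#'   (fully disrupted fibres), white matter follows the smooth field.
#' @param jitter_frac correlation length of the dispersion fields as a
#'   fraction of the frame height.
#' @param lesion_frac lesion radius as a fraction of the frame height
#'   (0 disables the lesion).
#' @param calib_perturb size of the random perturbation of the identity
#'   used for the simulated calibration matrices (condition number < 10).
#' @param seed top-level seed; all phantom randomness derives from it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(h = 384, w = 512,
                         optics = NULL,
                         sigma = 0.08, kappa = 0.05, wmult = 3,
                         n_shots = 16L,
                         smooth_frac = 0.12, orient_frac = 0.2,
                         gm_disp = 25, ti_disp = 50, jitter_frac = 0.05,
                         lesion_frac = 0.18,
                         calib_perturb = 0.1,
                         seed = 1L) {
  default_optics <- list(
    background          = list(delta = 0,  diag = c(0.02, 0.02, 0.02), d = 0),
    grey_matter         = list(delta = 10, diag = c(0.70, 0.70, 0.65), d = 0.03),
    white_matter        = list(delta = 40, diag = c(0.85, 0.85, 0.80), d = 0.05),
    tumour_centre       = list(delta = 8,  diag = c(0.60, 0.60, 0.55), d = 0.03),
    tumour_infiltration = list(delta = 24, diag = c(0.72, 0.72, 0.67), d = 0.04))
  if (is.null(optics)) optics <- default_optics
  for (nm in names(PHANTOM_CLASSES)) {
    o <- optics[[nm]]
    if (is.null(o)) stop("missing optics for class ", nm)
    if (o$delta < 0 || o$delta >= 180) stop("delta out of [0, 180) for ", nm)
    if (any(o$diag <= 0) || any(o$diag > 1)) stop("depolariser diagonal out of (0, 1] for ", nm)
    if (o$d < 0 || o$d >= 1) stop("|d| must be < 1 for ", nm)
  }
  stopifnot(sigma >= 0, kappa >= 0, kappa < 1, wmult > 1, n_shots >= 1)
  structure(list(h = h, w = w, optics = optics, sigma = sigma,
                 kappa = kappa, wmult = wmult, n_shots = as.integer(n_shots),
                 smooth_frac = smooth_frac, orient_frac = orient_frac,
                 gm_disp = gm_disp, ti_disp = ti_disp,
                 jitter_frac = jitter_frac,
                 lesion_frac = lesion_frac, calib_perturb = calib_perturb,
                 seed = seed),
            class = "phantom_spec")
}

#' Pseudo-Gaussian acquisition noise
#'
#' Zero-mean Gaussian scale mixture: with probability `1 - kappa` a draw
#' from N(0, sigma^2), with probability `kappa` from N(0, (wmult sigma)^2).
#' The mixture is symmetric, zero-mean and bell-shaped, with a cumulative
#' distribution deviating slightly from the normal reference (positive
#' excess kurtosis) when `kappa > 0`. Draws use the current RNG state.
#'
#' @param dim integer vector of array dimensions.
#' @param sigma core standard deviation (>= 0).
#' @param kappa contamination fraction in [0, 1).
#' @param wmult contamination width multiplier (> 1).
#' @return array of the requested dimension.
#' @export
sample_noise <- function(dim, sigma, kappa = 0, wmult = 3) {
  stopifnot(sigma >= 0, kappa >= 0, kappa < 1, wmult > 1)
  n <- prod(dim)
  if (sigma == 0) return(array(0, dim))
  sd <- ifelse(stats::runif(n) < kappa, wmult * sigma, sigma)
  array(stats::rnorm(n, 0, sd), dim)
}

#' Average the first n single-shot acquisitions
#'
#' @param shots list of [intensity_tensor()]s of equal size.
#' @param n number of shots to average (n <= length(shots)).
#' @return an [intensity_tensor()] with `shots = n` metadata.
#' @export
average_shots <- function(shots, n) {
  if (n > length(shots)) {
    stop("requested average of ", n, " shots but only ",
         length(shots), " available")
  }
  acc <- unclass(shots[[1]])
  if (n > 1) for (k in 2:n) acc <- acc + unclass(shots[[k]])
  intensity_tensor(acc / n, shots = n,
                   meta = attr(shots[[1]], "meta"))
}

## Batched linear-retarder matrices for per-pixel theta (deg) and delta (deg).
batch_linear_retarder <- function(theta, delta) {
  n <- length(theta)
  t2 <- 2 * theta * pi / 180; dl <- delta * pi / 180
  c2 <- cos(t2); s2 <- sin(t2); cd <- cos(dl); sd <- sin(dl)
  LR <- array(0, c(n, 4, 4))
  LR[, 1, 1] <- 1
  LR[, 2, 2] <- c2^2 + s2^2 * cd
  LR[, 2, 3] <- c2 * s2 * (1 - cd)
  LR[, 2, 4] <- -s2 * sd
  LR[, 3, 2] <- LR[, 2, 3]
  LR[, 3, 3] <- s2^2 + c2^2 * cd
  LR[, 3, 4] <- c2 * sd
  LR[, 4, 2] <- s2 * sd
  LR[, 4, 3] <- -c2 * sd
  LR[, 4, 4] <- cd
  LR
}

## Batched canonical diattenuators from n x 3 diattenuation vectors.
batch_diattenuator <- function(dvec) {
  n <- nrow(dvec)
  D <- sqrt(rowSums(dvec^2))
  r <- sqrt(pmax(1 - D^2, 0))
  dh <- dvec / ifelse(D > 0, D, 1)
  MD <- array(0, c(n, 4, 4))
  MD[, 1, 1] <- 1
  for (i in 1:3) {
    MD[, 1, 1 + i] <- dvec[, i]
    MD[, 1 + i, 1] <- dvec[, i]
    for (j in 1:3) MD[, 1 + i, 1 + j] <- (1 - r) * dh[, i] * dh[, j] + (i == j) * r
  }
  MD
}

#' Generate a synthetic polarimetric acquisition set
#'
#' Realises a [phantom_spec()]: draws the tissue-class map (thresholded
#' smoothed noise blobs plus a lesion disk with an infiltration ring), the
#' fibre-orientation field, composes per-pixel ground-truth Mueller
#' matrices `M = M_Delta(class) LR(theta, delta(class)) M_D(class)`, images
#' them through randomly perturbed calibration matrices, and simulates
#' `n_shots` noisy acquisitions plus their n-shot averages.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `acquisition_set`: list with `class_map`
#'   (H x W integer, see `PHANTOM_CLASSES`), `orientation` (degrees),
#'   `ground_truth_M` ([mueller_image()]), `gt_params`
#'   (analytic [scalar_params()]-style maps), `calib`
#'   ([calibration_pair()]), `shots` (list of [intensity_tensor()]),
#'   `averaged` (named list for n = 1, 8, 16), `clean`
#'   (noise-free intensities) and `roi` (logical, excludes background).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$h; w <- spec$w; n <- h * w

  geom <- with_seed(child_seed(spec$seed, 1), {
    f_bg <- gauss_smooth(matrix(stats::rnorm(n), h, w), spec$smooth_frac * h)
    f_gw <- gauss_smooth(matrix(stats::rnorm(n), h, w), spec$smooth_frac * h)
    cls <- matrix(PHANTOM_CLASSES[["grey_matter"]], h, w)
    cls[f_gw >= stats::median(f_gw)] <- PHANTOM_CLASSES[["white_matter"]]
    cls[f_bg < stats::quantile(f_bg, 0.15)] <- PHANTOM_CLASSES[["background"]]
    if (spec$lesion_frac > 0) {
      wm <- which(cls == PHANTOM_CLASSES[["white_matter"]], arr.ind = TRUE)
      centre <- if (nrow(wm)) wm[sample.int(nrow(wm), 1), ] else c(h / 2, w / 2)
      rad <- spec$lesion_frac * h
      dist <- sqrt(outer(seq_len(h) - centre[1], rep(1, w))^2 +
                   outer(rep(1, h), seq_len(w) - centre[2])^2)
      tissue <- cls != PHANTOM_CLASSES[["background"]]
      cls[tissue & dist <= rad] <- PHANTOM_CLASSES[["tumour_infiltration"]]
      cls[tissue & dist <= 0.6 * rad] <- PHANTOM_CLASSES[["tumour_centre"]]
    }
    u <- gauss_smooth(matrix(stats::rnorm(n), h, w), spec$orient_frac * h)
    v <- gauss_smooth(matrix(stats::rnorm(n), h, w), spec$orient_frac * h)
    theta <- wrap_axial(0.5 * atan2(v, u) * 180 / pi)
    ## spatially correlated dispersion (fibre fanning has spatial extent;
    ## pixel-iid jitter would be unphysical and unrecoverable by any
    ## denoiser); unit-variance smooth field scaled per class
    jf <- gauss_smooth(matrix(stats::rnorm(n), h, w), spec$jitter_frac * h)
    jf <- jf / stats::sd(jf)
    gm <- cls == PHANTOM_CLASSES[["grey_matter"]]
    ti <- cls == PHANTOM_CLASSES[["tumour_infiltration"]]
    tc <- cls == PHANTOM_CLASSES[["tumour_centre"]]
    jitter <- matrix(0, h, w)
    jitter[gm] <- spec$gm_disp * jf[gm]
    jitter[ti] <- spec$ti_disp * jf[ti]
    theta <- wrap_axial(theta + jitter)
    theta[tc] <- stats::runif(sum(tc), 0, 180)
    list(cls = cls, theta = theta)
  })
  cls <- geom$cls; theta <- geom$theta

  ## per-pixel optics from the class map
  delta <- matrix(0, h, w); dmag <- matrix(0, h, w)
  da <- db <- dc <- matrix(0, h, w)
  for (nm in names(PHANTOM_CLASSES)) {
    sel <- cls == PHANTOM_CLASSES[[nm]]
    o <- spec$optics[[nm]]
    delta[sel] <- o$delta; dmag[sel] <- o$d
    da[sel] <- o$diag[1]; db[sel] <- o$diag[2]; dc[sel] <- o$diag[3]
  }

  t2 <- 2 * as.vector(theta) * pi / 180
  dvec <- cbind(as.vector(dmag) * cos(t2), as.vector(dmag) * sin(t2), 0)
  MD <- batch_diattenuator(dvec)
  LR <- batch_linear_retarder(as.vector(theta), as.vector(delta))
  MDel <- array(0, c(n, 4, 4))
  MDel[, 1, 1] <- 1
  MDel[, 2, 2] <- as.vector(da); MDel[, 3, 3] <- as.vector(db)
  MDel[, 4, 4] <- as.vector(dc)
  Mp <- bmm(bmm(MDel, LR), MD)
  roi <- cls != PHANTOM_CLASSES[["background"]]
  M <- pix_to_mueller(Mp, h, w, normalised = TRUE, valid = roi)

  calib <- with_seed(child_seed(spec$seed, 2), {
    draw <- function() diag(4) + matrix(stats::rnorm(16, 0, spec$calib_perturb), 4)
    repeat {
      G <- draw(); A <- draw()
      kG <- cond44(array(G, c(1, 4, 4))); kA <- cond44(array(A, c(1, 4, 4)))
      if (is.finite(kG) && is.finite(kA) && kG < 10 && kA < 10) break
    }
    calibration_pair(G, A)
  })

  clean <- forward_intensities(M, calib)
  shots <- with_seed(child_seed(spec$seed, 3), {
    lapply(seq_len(spec$n_shots), function(k) {
      intensity_tensor(unclass(clean) +
                         sample_noise(dim(clean), spec$sigma, spec$kappa,
                                      spec$wmult),
                       shots = 1L, meta = list(shot = k, seed = spec$seed))
    })
  })
  averaged <- list()
  for (nn in c(1L, 8L, 16L)) {
    if (nn <= length(shots)) averaged[[as.character(nn)]] <- average_shots(shots, nn)
  }

  gt_params <- structure(list(
    D = dmag, Delta = 1 - (da + db + dc) / 3, R = delta,
    phi = wrap_axial(theta), valid = roi,
    phi_defined = roi & delta > 0), class = "parameter_maps")

  structure(list(class_map = cls, orientation = theta,
                 ground_truth_M = M, gt_params = gt_params, calib = calib,
                 clean = clean, shots = shots, averaged = averaged,
                 roi = roi, spec = spec),
            class = "acquisition_set")
}

#' @export
print.acquisition_set <- function(x, ...) {
  tab <- table(factor(x$class_map, levels = PHANTOM_CLASSES,
                      labels = names(PHANTOM_CLASSES)))
  cat(sprintf("<acquisition_set %d x %d, %d shots, sigma = %g>\n",
              x$spec$h, x$spec$w, length(x$shots), x$spec$sigma))
  print(tab)
  invisible(x)
}
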