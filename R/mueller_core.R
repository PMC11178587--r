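## Forward and inverse polarimetric imaging model.
##
## Per pixel the camera measures I = A M G, where M is the tissue Mueller
## matrix and G, A are the calibrated generator/analyser matrices. The
## inverse map M = A^-1 I G^-1 is solved in closed form with the batched
## cofactor inverse of arrays.R, so a whole frame is one vectorised pass.

#' Derive per-pixel Mueller matrices from measured intensities
#'
#' Solves `M = A^-1 I G^-1` for every pixel. The 4 x 4 inversions use a
#' closed-form cofactor expansion vectorised over pixels; no per-pixel loop
#' is involved.
#'
#' @param I an [intensity_tensor()] (H x W x 16) or a plain H x W x 16
#'   array.
#' @param calib a [calibration_pair()].
#' @return a [mueller_image()] (not yet M11-normalised).
#' @seealso [forward_intensities()] for the forward model,
#'   [normalise_m11()] for the conventional normalisation.
#' @export
derive_mueller <- function(I, calib) {
  stopifnot(inherits(calib, "calibration_pair"))
  d <- dim(I)
  if (length(d) != 3L || d[3] != 16L) stop("expected 16 channels")
  h <- d[1]; w <- d[2]
  Ip <- stack_to_mats(unclass(I))
  if (calib$mode == "global") {
    Ainv <- inv44(array(calib$A, c(1, 4, 4)))$inv[1, , ]
    Ginv <- inv44(array(calib$G, c(1, 4, 4)))$inv[1, , ]
    Mp <- bmm_right(bmm_left(Ainv, Ip), Ginv)
  } else {
    n <- h * w
    Ga <- array(calib$G, c(n, 4, 4))
    Aa <- array(calib$A, c(n, 4, 4))
    gi <- inv44(Ga); ai <- inv44(Aa)
    Mp <- bmm(bmm(ai$inv, Ip), gi$inv)
  }
  pix_to_mueller(Mp, h, w, normalised = FALSE)
}

#' Simulate measured intensities from a Mueller image
#'
#' The forward imaging model `I = A M G` applied per pixel; inverse of
#' [derive_mueller()].
#'
#' @param M a [mueller_image()].
#' @param calib a [calibration_pair()].
#' @param shots shot count recorded in the result's metadata.
#' @return an [intensity_tensor()].
#' @export
forward_intensities <- function(M, calib, shots = 1L) {
  stopifnot(inherits(calib, "calibration_pair"))
  d <- dim(M)
  h <- d[1]; w <- d[2]
  Mp <- mueller_pix(M)
  if (calib$mode == "global") {
    Ip <- bmm_right(bmm_left(calib$A, Mp), calib$G)
  } else {
    n <- h * w
    Ip <- bmm(bmm(array(calib$A, c(n, 4, 4)), Mp), array(calib$G, c(n, 4, 4)))
  }
  intensity_tensor(mats_to_stack(Ip, h, w), shots = shots)
}

#' Normalise a Mueller image by its M11 element
#'
#' Divides every 4 x 4 block by its (1,1) element, the conventional
#' normalisation that makes diattenuation and depolarisation dimensionless.
#' Pixels with |M11| <= eps are flagged invalid and left untouched.
#'
#' @param M a [mueller_image()].
#' @param eps threshold below which M11 is treated as zero.
#' @return a [mueller_image()] with `normalised = TRUE`; the validity mask
#'   excludes near-zero-M11 pixels.
#' @export
normalise_m11 <- function(M, eps = 1e-12) {
  d <- dim(M)
  m11 <- unclass(M)[, , 1, 1]
  ok <- attr(M, "valid") & is.finite(m11) & abs(m11) > eps
  out <- unclass(M)
  scale <- ifelse(ok, m11, 1)
  out <- out / as.vector(scale)  # recycles over the trailing 4 x 4 dims
  keep <- array(rep(!ok, 16L), d)
  out[keep] <- unclass(M)[keep]
  mueller_image(array(out, d), normalised = TRUE, valid = ok)
}
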