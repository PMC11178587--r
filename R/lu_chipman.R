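## Lu-Chipman polar decomposition M = M_Delta M_R M_D and the scalar
## polarimetric parameter maps derived from the factors.
##
## The factor order (diattenuator first, then retarder, depolariser last in
## the product read right-to-left) is the classical one; the coefficient
## indices of the scalar-parameter formulas presuppose exactly these
## factors. The diattenuator is removed analytically, the depolariser is
## the signed symmetric square root of m' m'^T (eigen decomposition), and
## the retarder is what remains.

#' Lu-Chipman decomposition of a Mueller image
#'
#' Factorises each pixel's Mueller matrix as `M = M_Delta M_R M_D`
#' (depolariser x retarder x diattenuator). Pixels where the decomposition
#' is numerically impossible (diattenuation >= 1, non-finite entries,
#' negative eigenvalues of m' m'^T beyond tolerance) are flagged invalid in
#' the result, never thrown: full frames with noisy background must
#' survive.
#'
#' @param M a [mueller_image()]; normalised with [normalise_m11()] first if
#'   it is not already (`M11 = 1` is a precondition of the factor formulas).
#' @param eig_tol eigenvalues of m' m'^T below `-eig_tol` mark a pixel
#'   invalid; values in `(-eig_tol, 0)` are clamped to zero.
#' @return an object of class `lu_chipman_factors`: list with H x W x 4 x 4
#'   arrays `M_D`, `M_R`, `M_Delta` and an H x W logical `valid`.
#' @references Lu, S.-Y. and Chipman, R. A., Interpretation of Mueller
#'   matrices based on polar decomposition, JOSA A 13, 1106 (1996).
#' @export
decompose <- function(M, eig_tol = 1e-9) {
  stopifnot(inherits(M, "mueller_image"))
  if (!attr(M, "normalised")) M <- normalise_m11(M)
  d <- dim(M); h <- d[1]; w <- d[2]; n <- h * w
  Mp <- mueller_pix(M)
  valid <- as.vector(attr(M, "valid"))
  valid <- valid & apply(is.finite(Mp), 1, all)

  dvec <- matrix(Mp[, 1, 2:4], n, 3)          # n x 3 diattenuation vectors
  D <- sqrt(rowSums(dvec^2))
  valid <- valid & is.finite(D) & D < 1

  ## Diattenuator M_D = [[1, d^T], [d, r I + (1-r) dh dh^T]], r = sqrt(1-D^2)
  r <- sqrt(pmax(1 - D^2, 0))
  dh <- dvec / ifelse(D > 0, D, 1)
  MD <- array(0, c(n, 4, 4))
  MD[, 1, 1] <- 1
  for (i in 1:3) {
    MD[, 1, 1 + i] <- dvec[, i]
    MD[, 1 + i, 1] <- dvec[, i]
    for (j in 1:3) {
      MD[, 1 + i, 1 + j] <- (1 - r) * dh[, i] * dh[, j] + (i == j) * r
    }
  }

  MDi <- inv44(MD)
  valid <- valid & is.finite(MDi$det) & abs(MDi$det) > 0
  MDi$inv[!is.finite(MDi$inv)] <- 0
  Mp[!is.finite(Mp)] <- 0
  Mprime <- bmm(Mp, MDi$inv)

  mp <- array(Mprime[, 2:4, 2:4], c(n, 3, 3))
  Pdelta <- matrix(Mprime[, 2:4, 1], n, 3)
  C <- bmm(mp, bt(mp))
  sgn <- ifelse(bdet3(mp) < 0, -1, 1)

  mDelta <- array(0, c(n, 3, 3))
  mR <- array(0, c(n, 3, 3))
  idx <- which(valid)
  for (k in idx) {
    Ck <- matrix(C[k, , ], 3, 3)
    e <- eigen((Ck + t(Ck)) / 2, symmetric = TRUE)
    lam <- e$values
    if (any(lam < -eig_tol)) { valid[k] <- FALSE; next }
    lam <- pmax(lam, 0)
    sq <- sqrt(lam)
    mDk <- sgn[k] * (e$vectors %*% (sq * t(e$vectors)))
    mDelta[k, , ] <- mDk
    if (all(sq > eig_tol)) {
      mDi <- sgn[k] * (e$vectors %*% ((1 / sq) * t(e$vectors)))
      mR[k, , ] <- mDi %*% matrix(mp[k, , ], 3, 3)
    } else {
      ## retarder undefined where m' is singular (fully depolarised axis)
      mR[k, , ] <- diag(3)
      valid[k] <- FALSE
    }
  }

  MDelta <- array(0, c(n, 4, 4)); MDelta[, 1, 1] <- 1
  MRf <- array(0, c(n, 4, 4)); MRf[, 1, 1] <- 1
  MDelta[, 2:4, 1] <- Pdelta
  MDelta[, 2:4, 2:4] <- mDelta
  MRf[, 2:4, 2:4] <- mR
  ## mark invalid pixels with identity factors to keep arrays finite
  bad <- which(!valid)
  if (length(bad)) {
    I4 <- diag(4)
    for (i in 1:4) for (j in 1:4) {
      MDelta[bad, i, j] <- I4[i, j]
      MRf[bad, i, j] <- I4[i, j]
      MD[bad, i, j] <- I4[i, j]
    }
  }

  structure(list(
    M_D = array(MD, c(h, w, 4, 4)),
    M_R = array(MRf, c(h, w, 4, 4)),
    M_Delta = array(MDelta, c(h, w, 4, 4)),
    valid = matrix(valid, h, w)
  ), class = "lu_chipman_factors")
}

#' Reassemble a Mueller image from Lu-Chipman factors
#'
#' Computes `M_Delta M_R M_D` per pixel; on valid pixels of a physical
#' input this reconstructs the decomposed matrix.
#'
#' @param f a `lu_chipman_factors` object from [decompose()].
#' @return a [mueller_image()].
#' @export
lc_reconstruct <- function(f) {
  stopifnot(inherits(f, "lu_chipman_factors"))
  d <- dim(f$M_D); h <- d[1]; w <- d[2]; n <- h * w
  p <- bmm(bmm(array(f$M_Delta, c(n, 4, 4)), array(f$M_R, c(n, 4, 4))),
           array(f$M_D, c(n, 4, 4)))
  pix_to_mueller(p, h, w, normalised = TRUE, valid = f$valid)
}

#' Scalar polarimetric parameter maps from Lu-Chipman factors
#'
#' Derives the four clinically used scalar maps per pixel:
#' total diattenuation `D = sqrt(M_D12^2 + M_D13^2 + M_D14^2)`,
#' total depolarisation `Delta = 1 - |tr(m_Delta)| / 3` over the 3 x 3
#' depolariser submatrix (a `trace` switch reproduces the variant over the
#' full 4 x 4 trace), scalar retardance
#' `R = acos(sqrt((M_R22 + M_R33)^2 + (M_R32 - M_R23)^2) - 1)` with the
#' inner argument clamped to \[-1, 1\], and the optical-axis azimuth
#' `phi = 1/2 atan2(-M_R24, -M_R43)` wrapped onto \[0, 180). The
#' quadrant-aware two-argument arctangent is used because the plain ratio
#' `M_R24 / M_R43` is 90-degree ambiguous; with the retarder convention of
#' [make_linear_retarder()] this form recovers the fast-axis azimuth
#' exactly.
#'
#' @param f a `lu_chipman_factors` object.
#' @param delta_trace `"sub3"` (default, 3 x 3 submatrix trace, guarantees
#'   Delta in \[0, 1\]) or `"full4"` (literal 4 x 4 trace variant).
#' @return an object of class `parameter_maps`: list of H x W matrices
#'   `D`, `Delta` (dimensionless), `R`, `phi` (degrees), logical `valid`,
#'   and `phi_defined` (FALSE where `sin(R)` is approximately 0, i.e. the
#'   azimuth is undefined).
#' @export
scalar_params <- function(f, delta_trace = c("sub3", "full4")) {
  stopifnot(inherits(f, "lu_chipman_factors"))
  delta_trace <- match.arg(delta_trace)
  d <- dim(f$M_D); h <- d[1]; w <- d[2]
  sl <- function(a, i, j) matrix(a[, , i, j], h, w)  # drop-safe element map

  D <- sqrt(sl(f$M_D, 1, 2)^2 + sl(f$M_D, 1, 3)^2 + sl(f$M_D, 1, 4)^2)
  tr3 <- sl(f$M_Delta, 2, 2) + sl(f$M_Delta, 3, 3) + sl(f$M_Delta, 4, 4)
  Delta <- if (delta_trace == "sub3") 1 - abs(tr3) / 3 else
    1 - abs(tr3 + sl(f$M_Delta, 1, 1)) / 3

  arg <- sqrt((sl(f$M_R, 2, 2) + sl(f$M_R, 3, 3))^2 +
              (sl(f$M_R, 3, 2) - sl(f$M_R, 2, 3))^2) - 1
  R <- acos(pmin(pmax(arg, -1), 1)) * 180 / pi

  phi <- wrap_axial(0.5 * atan2(-sl(f$M_R, 2, 4), -sl(f$M_R, 4, 3)) * 180 / pi)
  phi_defined <- f$valid & (sin(R * pi / 180) > 1e-9)

  structure(list(D = D, Delta = Delta, R = R, phi = phi,
                 valid = f$valid, phi_defined = phi_defined),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps %d x %d, %d valid px>\n",
              nrow(x$D), ncol(x$D), sum(x$valid)))
  for (nm in c("D", "Delta", "R", "phi")) {
    v <- x[[nm]][x$valid]
    if (length(v)) {
      cat(sprintf("  %-5s median %.4g  [%.4g, %.4g]\n", nm,
                  stats::median(v), min(v), max(v)))
    }
  }
  invisible(x)
}
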