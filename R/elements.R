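## Analytic Mueller matrices of canonical optical elements.
##
## These serve three roles: building blocks of the synthetic phantom,
## analytic oracles for the decomposition tests, and documentation of the
## sign conventions used throughout the package.

#' Mueller matrix of an ideal linear retarder
#'
#' Fast axis at azimuth `theta`, retardance `delta`, both in degrees. The
#' sign convention is fixed by the quarter-wave plate at `theta = 0`,
#' `delta = 90`: rows (1,0,0,0), (0,1,0,0), (0,0,0,1), (0,0,-1,0).
#' With this convention [scalar_params()] of [decompose()] recovers
#' `R = delta` and `phi = theta`.
#'
#' @param theta fast-axis azimuth in degrees (axial, modulo 180).
#' @param delta retardance in degrees, in \[0, 180\].
#' @return a 4 x 4 Mueller matrix.
#' @export
make_linear_retarder <- function(theta, delta) {
  t2 <- 2 * theta * pi / 180
  dl <- delta * pi / 180
  c2 <- cos(t2); s2 <- sin(t2)
  cd <- cos(dl); sd <- sin(dl)
  matrix(c(
    1, 0,                       0,                       0,
    0, c2^2 + s2^2 * cd,        c2 * s2 * (1 - cd),     -s2 * sd,
    0, c2 * s2 * (1 - cd),      s2^2 + c2^2 * cd,        c2 * sd,
    0, s2 * sd,                -c2 * sd,                 cd
  ), 4, 4, byrow = TRUE)
}

#' Mueller matrix of a canonical diattenuator
#'
#' Built from a diattenuation vector `dvec` with |dvec| < 1; the first row
#' of the result is (1, dvec) and its total diattenuation D equals |dvec|.
#'
#' @param dvec numeric length-3 diattenuation vector.
#' @return a 4 x 4 Mueller matrix.
#' @export
make_diattenuator <- function(dvec) {
  stopifnot(length(dvec) == 3L)
  D <- sqrt(sum(dvec^2))
  if (D >= 1) stop("|dvec| must be < 1")
  if (D == 0) return(diag(4))
  dh <- dvec / D
  r <- sqrt(1 - D^2)
  mD <- r * diag(3) + (1 - r) * (dh %o% dh)
  out <- diag(4)
  out[1, 2:4] <- dvec
  out[2:4, 1] <- dvec
  out[2:4, 2:4] <- mD
  out
}

#' Mueller matrix of a diagonal depolariser
#'
#' `diag(1, a, b, c)` with principal depolarisation factors in (0, 1];
#' optionally with a polarizance vector in the first column.
#'
#' @param abc numeric length-3 vector of depolarisation diagonal entries.
#' @param pvec optional length-3 polarizance vector (default zero).
#' @return a 4 x 4 Mueller matrix.
#' @export
make_depolariser <- function(abc, pvec = c(0, 0, 0)) {
  stopifnot(length(abc) == 3L, length(pvec) == 3L)
  out <- diag(c(1, abc))
  out[2:4, 1] <- pvec
  out
}
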