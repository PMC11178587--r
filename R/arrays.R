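## Batched 4x4 linear algebra over pixel stacks.
##
## Pixel stacks are arrays of dimension (N, 4, 4) where N = H*W. All
## operations are vectorised over the first index; the 4x4 algebra is
## unrolled so the total cost is O(N) with constant-size inner products.

#' Map a (generator, analyser) state pair to its channel index
#'
#' The 16 polarisation states of an intensity stack are ordered row-major
#' over (generator state g = 1..4, analyser state a = 1..4), i.e. channel
#' `(g - 1) * 4 + a`. In matrix form, channel k holds the intensity
#' `I[a, g]` of Mueller calculus (rows indexed by the analyser, columns by
#' the generator), so that per pixel `I = A M G`. This function is the one
#' place where the convention is defined.
#'
#' @param g generator state index in 1..4.
#' @param a analyser state index in 1..4.
#' @return channel index in 1..16.
#' @export
state_channel <- function(g, a) {
  stopifnot(all(g %in% 1:4), all(a %in% 1:4))
  (g - 1L) * 4L + a
}

## H x W x 16 channels-last <-> N x 4 x 4 matrix stack (rows = analyser,
## cols = generator). Inverse of each other by construction.
stack_to_mats <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L, d[3] == 16L)
  n <- d[1] * d[2]
  out <- array(0, c(n, 4L, 4L))
  for (g in 1:4) for (a in 1:4) {
    out[, a, g] <- x[, , state_channel(g, a)]
  }
  out
}

mats_to_stack <- function(m, h, w) {
  stopifnot(length(dim(m)) == 3L, dim(m)[2] == 4L, dim(m)[3] == 4L,
            dim(m)[1] == h * w)
  out <- array(0, c(h, w, 16L))
  for (g in 1:4) for (a in 1:4) {
    out[, , state_channel(g, a)] <- m[, a, g]
  }
  out
}

## Batched matrix product Z[n,,] = X[n,,] %*% Y[n,,] for k x k blocks.
bmm <- function(x, y) {
  dx <- dim(x); dy <- dim(y)
  stopifnot(length(dx) == 3L, length(dy) == 3L, dx[3] == dy[2],
            dx[1] == dy[1])
  k1 <- dx[2]; k2 <- dy[3]; kk <- dx[3]
  z <- array(0, c(dx[1], k1, k2))
  for (i in seq_len(k1)) for (j in seq_len(k2)) {
    acc <- x[, i, 1] * y[, 1, j]
    for (k in seq_len(kk)[-1]) acc <- acc + x[, i, k] * y[, k, j]
    z[, i, j] <- acc
  }
  z
}

## Batched product with a single (global) matrix on the right: X[n,,] %*% B.
bmm_right <- function(x, b) {
  d <- dim(x)
  stopifnot(length(d) == 3L, d[3] == nrow(b))
  array(matrix(x, d[1] * d[2], d[3]) %*% b, c(d[1], d[2], ncol(b)))
}

## Batched product with a single matrix on the left: B %*% X[n,,].
bmm_left <- function(b, x) {
  d <- dim(x)
  stopifnot(length(d) == 3L, ncol(b) == d[2])
  z <- array(0, c(d[1], nrow(b), d[3]))
  for (j in seq_len(d[3])) z[, , j] <- x[, , j] %*% t(b)
  z
}

bt <- function(x) aperm(x, c(1L, 3L, 2L))

## Batched determinant of 3x3 blocks.
bdet3 <- function(x) {
  x[, 1, 1] * (x[, 2, 2] * x[, 3, 3] - x[, 2, 3] * x[, 3, 2]) -
  x[, 1, 2] * (x[, 2, 1] * x[, 3, 3] - x[, 2, 3] * x[, 3, 1]) +
  x[, 1, 3] * (x[, 2, 1] * x[, 3, 2] - x[, 2, 2] * x[, 3, 1])
}

## Closed-form batched 4x4 inverse by cofactor expansion (adjugate over
## 2x2 pair determinants). det is returned so callers can flag singular
## blocks; entries of singular blocks are NaN/Inf and must be masked.
inv44 <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == 4L, dim(x)[3] == 4L)
  m <- function(i, j) x[, i, j]
  s1 <- m(1,1)*m(2,2) - m(1,2)*m(2,1)
  s2 <- m(1,1)*m(2,3) - m(1,3)*m(2,1)
  s3 <- m(1,1)*m(2,4) - m(1,4)*m(2,1)
  s4 <- m(1,2)*m(2,3) - m(1,3)*m(2,2)
  s5 <- m(1,2)*m(2,4) - m(1,4)*m(2,2)
  s6 <- m(1,3)*m(2,4) - m(1,4)*m(2,3)
  c1 <- m(3,1)*m(4,2) - m(3,2)*m(4,1)
  c2 <- m(3,1)*m(4,3) - m(3,3)*m(4,1)
  c3 <- m(3,1)*m(4,4) - m(3,4)*m(4,1)
  c4 <- m(3,2)*m(4,3) - m(3,3)*m(4,2)
  c5 <- m(3,2)*m(4,4) - m(3,4)*m(4,2)
  c6 <- m(3,3)*m(4,4) - m(3,4)*m(4,3)
  det <- s1*c6 - s2*c5 + s3*c4 + s4*c3 - s5*c2 + s6*c1
  inv <- array(0, dim(x))
  inv[, 1, 1] <-  m(2,2)*c6 - m(2,3)*c5 + m(2,4)*c4
  inv[, 1, 2] <- -m(1,2)*c6 + m(1,3)*c5 - m(1,4)*c4
  inv[, 1, 3] <-  m(4,2)*s6 - m(4,3)*s5 + m(4,4)*s4
  inv[, 1, 4] <- -m(3,2)*s6 + m(3,3)*s5 - m(3,4)*s4
  inv[, 2, 1] <- -m(2,1)*c6 + m(2,3)*c3 - m(2,4)*c2
  inv[, 2, 2] <-  m(1,1)*c6 - m(1,3)*c3 + m(1,4)*c2
  inv[, 2, 3] <- -m(4,1)*s6 + m(4,3)*s3 - m(4,4)*s2
  inv[, 2, 4] <-  m(3,1)*s6 - m(3,3)*s3 + m(3,4)*s2
  inv[, 3, 1] <-  m(2,1)*c5 - m(2,2)*c3 + m(2,4)*c1
  inv[, 3, 2] <- -m(1,1)*c5 + m(1,2)*c3 - m(1,4)*c1
  inv[, 3, 3] <-  m(4,1)*s5 - m(4,2)*s3 + m(4,4)*s1
  inv[, 3, 4] <- -m(3,1)*s5 + m(3,2)*s3 - m(3,4)*s1
  inv[, 4, 1] <- -m(2,1)*c4 + m(2,2)*c2 - m(2,3)*c1
  inv[, 4, 2] <-  m(1,1)*c4 - m(1,2)*c2 + m(1,3)*c1
  inv[, 4, 3] <- -m(4,1)*s4 + m(4,2)*s2 - m(4,3)*s1
  inv[, 4, 4] <-  m(3,1)*s4 - m(3,2)*s2 + m(3,3)*s1
  list(inv = inv / det, det = det)
}

## Frobenius condition number kappa_F = ||A||_F ||A^-1||_F of 4x4 blocks.
cond44 <- function(x) {
  iv <- inv44(x)
  nf <- sqrt(apply(x^2, 1, sum))
  ni <- sqrt(apply(iv$inv^2, 1, sum))
  out <- nf * ni
  out[!is.finite(out) | abs(iv$det) == 0] <- Inf
  out
}

## Wrap angles (degrees) onto the axial interval [0, 180).
wrap_axial <- function(deg) deg %% 180

## Signed axial difference in (-90, 90].
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  d - 180 * (d > 90)
}
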