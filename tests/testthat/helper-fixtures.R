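# Shared fixtures, built once per test run.

# Random physically valid Mueller pixel: depolariser x retarder x
# diattenuator with parameters away from degeneracies.
random_physical_mueller <- function(dmax = 0.8, diag_min = 0.3) {
  th <- stats::runif(1, 0, 180)
  dl <- stats::runif(1, 5, 175)
  dv <- stats::runif(3, -0.5, 0.5)
  nd <- sqrt(sum(dv^2))
  if (nd > dmax) dv <- dv * dmax / nd
  ab <- stats::runif(3, diag_min, 1)
  make_depolariser(ab) %*% make_linear_retarder(th, dl) %*%
    make_diattenuator(dv)
}

# n x 4 x 4 stack of random physical Mueller pixels as a mueller_image
# of size h x w (n = h * w).
random_mueller_image <- function(h, w, dmax = 0.8) {
  p <- array(0, c(h * w, 4, 4))
  for (k in seq_len(h * w)) p[k, , ] <- random_physical_mueller(dmax)
  mueller_image(array(p, c(h, w, 4, 4)), normalised = TRUE)
}

random_calibration <- function(perturb = 0.1) {
  repeat {
    G <- diag(4) + matrix(stats::rnorm(16, 0, perturb), 4)
    A <- diag(4) + matrix(stats::rnorm(16, 0, perturb), 4)
    ok <- tryCatch({
      calibration_pair(G, A, max_cond = 100)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(calibration_pair(G, A, max_cond = 100))
  }
}

# One small phantom shared by several test files (cheap to build).
shared_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_phantom(phantom_spec(h = 64, w = 64, seed = 42))
    ph
  }
})

as1x1 <- function(M) mueller_image(array(M, c(1, 1, 4, 4)), normalised = TRUE)
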