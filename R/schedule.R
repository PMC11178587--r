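## Forward-diffusion variance schedule and the closed-form corruption
## sampler. The forward process is a Markov chain of Gaussian corruptions
## x_t ~ N(sqrt(1 - beta_t) x_{t-1}, beta_t J); its marginal given x_0 has
## the closed form x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) eps with
## abar_t the cumulative product of (1 - beta_s).

#' Build a diffusion variance schedule
#'
#' Linear beta schedule between `beta_start` and `beta_end` over `T`
#' time-points (the canonical choice for denoising diffusion models), with
#' the derived `alpha = 1 - beta` and cumulative `alpha_bar` sequences.
#'
#' @param T number of time-points (default 1000).
#' @param beta_start,beta_end schedule endpoints, 0 < start <= end < 1.
#' @return an object of class `diffusion_schedule`: list with `T`, `beta`,
#'   `alpha`, `alpha_bar` (all length `T`). `alpha_bar` is strictly
#'   decreasing with `alpha_bar[1]` close to 1.
#' @export
make_schedule <- function(T = 1000L, beta_start = 1e-4, beta_end = 0.02) {
  stopifnot(T >= 1)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("schedule endpoints must satisfy 0 < beta_start <= beta_end < 1")
  }
  beta <- seq(beta_start, beta_end, length.out = T)
  alpha <- 1 - beta
  structure(list(T = as.integer(T), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha),
                 beta_start = beta_start, beta_end = beta_end),
            class = "diffusion_schedule")
}

#' Sample a forward-diffusion state in closed form
#'
#' `x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) eps`, the marginal of the
#' forward Markov chain at time-point `t` given the clean image `x_0`.
#'
#' @param x0 clean image/patch, values in \[-1, 1\].
#' @param t time-point index in 1..T.
#' @param eps standard-normal noise array with the shape of `x0`.
#' @param sched a [make_schedule()] object.
#' @return corrupted state of the same shape as `x0`.
#' @export
q_sample <- function(x0, t, eps, sched) {
  stopifnot(inherits(sched, "diffusion_schedule"))
  if (t < 1 || t > sched$T) stop("t out of range 1..", sched$T)
  ab <- sched$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Invert q_sample given a noise estimate
#'
#' The x0-form single-step reconstruction
#' `x0_hat = (x_t - sqrt(1 - abar_t) eps_hat) / sqrt(abar_t)`; exact when
#' `eps_hat` is the noise actually used in [q_sample()].
#'
#' @param xt corrupted state.
#' @param t time-point index.
#' @param eps_hat noise estimate (e.g. network prediction).
#' @param sched a [make_schedule()] object.
#' @param clip clip the reconstruction into \[-1, 1\] (the model's data
#'   range); disable for algebraic identity checks.
#' @return reconstructed clean state.
#' @export
x0_from_eps <- function(xt, t, eps_hat, sched, clip = TRUE) {
  ab <- sched$alpha_bar[t]
  x0 <- (xt - sqrt(1 - ab) * eps_hat) / sqrt(ab)
  if (clip) x0 <- pmin(pmax(x0, -1), 1)
  x0
}
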