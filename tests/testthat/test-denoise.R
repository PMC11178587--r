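test_that("baseline filters honour their kernel contracts", {
  const <- array(3.3, c(12, 12, 16))
  for (m in c("MEDF", "GBLR", "GRAD")) {
    expect_equal(baseline_filter(const, m), const, tolerance = 1e-12)
  }
  # median of {1..8, 100} is 5 (robust to the outlier)
  x <- matrix(c(1, 2, 3, 4, 100, 5, 6, 7, 8), 3, 3)
  expect_equal(baseline_filter(x, "MEDF")[2, 2], 5)
  # brute-force sort oracle on random fields
  set.seed(51)
  y <- matrix(rnorm(15 * 15), 15)
  got <- baseline_filter(y, "MEDF")
  yp <- muellerpol:::pad2(y, 1, "replicate")
  for (i in c(1, 7, 15)) for (j in c(1, 8, 15)) {
    expect_equal(got[i, j], stats::median(yp[i:(i + 2), j:(j + 2)]))
  }
  # Gaussian kernel has unit DC gain
  expect_equal(sum(muellerpol:::gaussian_kernel(5, 1)), 1, tolerance = 1e-12)
  expect_error(baseline_filter(y, "NOPE"), "arg")
})

test_that("channel-wise baselines commute with channel permutation", {
  set.seed(52)
  x <- array(rnorm(10 * 10 * 16), c(10, 10, 16))
  perm <- sample(16)
  for (m in c("MEDF", "GBLR", "GRAD")) {
    expect_equal(baseline_filter(x, m)[, , perm],
                 baseline_filter(x[, , perm], m), tolerance = 1e-12)
  }
})

test_that("the diffusion denoiser couples channels (unlike the baselines)", {
  model <- pddn_model(width = 8, mults = c(1, 2), seed = 5)
  model$pars[["head.conv.W"]][] <- rnorm(length(model$pars[["head.conv.W"]]),
                                         0, 0.05)
  set.seed(53)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  perm <- c(16:1)
  a <- pddn_predict(model, x, 3)[, , perm]
  b <- pddn_predict(model, x[, , perm], 3)
  expect_gt(max(abs(a - b)), 1e-6)
})

test_that("mask_reflections flags and dilates saturated pixels", {
  x <- array(0, c(9, 9, 16))
  expect_false(any(mask_reflections(x, threshold = 0.5)))
  x[5, 5, ] <- 10
  m <- mask_reflections(x, threshold = 0.5, dilate = 1)
  expect_true(all(m[4:6, 4:6]))
  expect_equal(sum(m), 9)
  # quantile threshold 1.0: nothing is supra-maximum
  set.seed(54)
  y <- array(runif(5 * 5 * 16), c(5, 5, 16))
  expect_false(any(mask_reflections(y, 1.0, quantile = TRUE)))
})

test_that("an untrained (zero-head) model makes single-pass a pure rescale", {
  model <- pddn_model(width = 8, mults = c(1, 2), seed = 6)
  sched <- make_schedule(50)
  set.seed(55)
  x <- array(runif(8 * 8 * 16, -0.9, 0.9), c(8, 8, 16))
  out <- denoise_single_pass(x, model, sched, t_star = 5)
  ab <- sched$alpha_bar[5]
  expect_equal(out, pmin(pmax(x / sqrt(ab), -1), 1), tolerance = 1e-12)
  expect_error(denoise_single_pass(x, model, sched, t_star = 0), "t_star")
  expect_error(denoise_single_pass(x, model, sched, t_star = 51), "t_star")
})

test_that("rescaling to [-1, 1] is invertible with recorded bounds", {
  set.seed(56)
  x <- array(runif(100, 2, 7), c(5, 5, 4))
  rs <- rescale_unit(x)
  expect_equal(range(rs$x), c(-1, 1))
  expect_equal(unrescale_unit(rs$x, rs$bounds), x, tolerance = 1e-12)
})

test_that("noise estimation and time-point matching are consistent", {
  set.seed(57)
  clean <- matrix(0.2, 64, 64)
  for (sg in c(0.02, 0.08)) {
    est <- estimate_sigma(clean + matrix(rnorm(64 * 64, 0, sg), 64))
    expect_equal(est, sg, tolerance = 0.15)
  }
  sched <- make_schedule(200)
  t1 <- select_tstar(0.01, sched)
  t2 <- select_tstar(0.1, sched)
  expect_gt(t2, t1)
  expect_equal(sqrt(1 - sched$alpha_bar[t2]), 0.1, tolerance = 0.05)
})

test_that("smoke training decreases the loss and is reproducible", {
  set.seed(58)
  frames <- list(array(runif(16 * 16 * 16, -1, 1), c(16, 16, 16)))
  cfg <- list(T = 50L, beta_start = 1e-4, beta_end = 0.02, width = 8L,
              mults = c(1L, 2L), attn_levels = 2L, patch = 16L, batch = 2L,
              steps = 120L, lr = 2e-3)
  m1 <- train_pddn(frames, cfg, seed = 3, log_every = 20L)
  expect_lt(utils::tail(m1$manifest$loss_curve, 1),
            m1$manifest$loss_curve[1])
  m2 <- train_pddn(frames, cfg, seed = 3, log_every = 20L)
  expect_identical(m1$manifest, m2$manifest)
  expect_identical(m1$pars, m2$pars)
})

test_that("tiled full-frame inference matches untiled on interior pixels", {
  set.seed(59)
  frames <- list(array(runif(32 * 32 * 16, -1, 1), c(32, 32, 16)))
  cfg <- list(T = 50L, beta_start = 1e-4, beta_end = 0.02, width = 8L,
              mults = c(1L, 2L), attn_levels = 2L, patch = 16L, batch = 2L,
              steps = 60L, lr = 2e-3)
  model <- train_pddn(frames, cfg, seed = 4,
                      bounds = list(min = -1, max = 1))
  x <- intensity_tensor(array(runif(32 * 32 * 16, -1, 1), c(32, 32, 16)))
  sched <- model$sched
  untiled <- denoise_single_pass(unclass(x), model, sched, t_star = 3)
  tiled <- denoise_frame(x, model, sched, t_star = 3, tile = 16, overlap = 8)
  interior <- 9:24
  err <- max(abs(unclass(tiled)[interior, interior, ] -
                 untiled[interior, interior, ]))
  # attention is global per tile, so tiling is only approximately local;
  # interior agreement must be small relative to the signal scale
  expect_lt(err, 0.08)
})
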