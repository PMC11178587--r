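test_that("phantom generation is deterministic given a seed", {
  s <- phantom_spec(h = 24, w = 24, seed = 5, lesion_frac = 0.25)
  a <- make_phantom(s)
  b <- make_phantom(s)
  expect_identical(a$class_map, b$class_map)
  expect_identical(a$orientation, b$orientation)
  expect_identical(unclass(a$shots[[3]]), unclass(b$shots[[3]]))
  expect_identical(unclass(a$averaged[["16"]]), unclass(b$averaged[["16"]]))
})

test_that("noiseless phantom recovers ground truth through the full chain", {
  ph <- make_phantom(phantom_spec(h = 24, w = 24, sigma = 0, kappa = 0,
                                  seed = 8))
  expect_equal(unclass(ph$averaged[["1"]]), unclass(ph$clean),
               ignore_attr = TRUE)
  p <- scalar_params(decompose(normalise_m11(
    derive_mueller(ph$averaged[["1"]], ph$calib))))
  roi <- ph$roi & p$valid & ph$gt_params$phi_defined
  expect_gt(sum(roi), 100)
  expect_lt(max(abs(axial_diff(p$phi[roi], ph$gt_params$phi[roi]))), 1e-6)
  expect_lt(max(abs(p$R[roi] - ph$gt_params$R[roi])), 1e-6)
  expect_lt(max(abs(p$D[roi] - ph$gt_params$D[roi])), 1e-6)
  expect_lt(max(abs(p$Delta[roi] - ph$gt_params$Delta[roi])), 1e-6)
})

test_that("single-class constant-orientation phantom yields that azimuth", {
  opt <- list(
    background          = list(delta = 0, diag = c(0.02, 0.02, 0.02), d = 0),
    grey_matter         = list(delta = 40, diag = c(0.85, 0.85, 0.8), d = 0.05),
    white_matter        = list(delta = 40, diag = c(0.85, 0.85, 0.8), d = 0.05),
    tumour_centre       = list(delta = 40, diag = c(0.85, 0.85, 0.8), d = 0.05),
    tumour_infiltration = list(delta = 40, diag = c(0.85, 0.85, 0.8), d = 0.05))
  ph <- make_phantom(phantom_spec(h = 16, w = 16, sigma = 0, kappa = 0,
                                  optics = opt, lesion_frac = 0,
                                  gm_disp = 0, ti_disp = 0, seed = 3))
  # overwrite with a constant field: rebuild M from the same machinery
  ph$orientation[] <- 30
  M <- muellerpol:::pix_to_mueller(
    muellerpol:::bmm(
      muellerpol:::bmm(
        array(rep(diag(c(1, 0.85, 0.85, 0.8)), each = 256), c(256, 4, 4)),
        muellerpol:::batch_linear_retarder(rep(30, 256), rep(40, 256))),
      muellerpol:::batch_diattenuator(
        cbind(rep(0.05 * cos(2 * 30 * pi / 180), 256),
              rep(0.05 * sin(2 * 30 * pi / 180), 256), 0))),
    16, 16, normalised = TRUE)
  I <- forward_intensities(M, ph$calib)
  p <- scalar_params(decompose(normalise_m11(derive_mueller(I, ph$calib))))
  expect_lt(max(abs(axial_diff(p$phi, 30))), 1e-6)
})

test_that("pseudo-Gaussian mixture noise has the closed-form moments", {
  set.seed(31)
  sigma <- 1; kappa <- 0.1; wm <- 3
  x <- sample_noise(c(200, 200, 4), sigma, kappa, wm)
  n <- length(x)
  # mixture variance sigma^2 (1 - kappa + kappa w^2)
  v_theory <- sigma^2 * (1 - kappa + kappa * wm^2)
  expect_equal(mean(x), 0, tolerance = 4 / sqrt(n))
  expect_equal(stats::sd(x), sqrt(v_theory), tolerance = 0.02 * sqrt(v_theory))
  # excess kurtosis from the mixture fourth moment: positive
  m4 <- 3 * sigma^4 * (1 - kappa + kappa * wm^4)
  ek_theory <- m4 / v_theory^2 - 3
  ek <- mean(x^4) / mean(x^2)^2 - 3
  expect_gt(ek_theory, 0)
  expect_equal(ek, ek_theory, tolerance = 0.25)
  # kappa = 0: Gaussian moments
  g <- sample_noise(c(1000, 1000), 1, 0, 3)
  expect_equal(mean(g^3), 0, tolerance = 0.02)
  expect_equal(mean(g^4) / mean(g^2)^2, 3, tolerance = 0.03)
  expect_identical(sample_noise(c(5, 5), 0, 0.2, 2), array(0, c(5, 5)))
})

test_that("shot averaging follows the 1/sqrt(n) law and its contract", {
  ph <- make_phantom(phantom_spec(h = 48, w = 48, kappa = 0, seed = 17))
  clean <- unclass(ph$clean)
  e <- sapply(c(1, 4, 8, 16), function(n) {
    sqrt(mean((unclass(average_shots(ph$shots, n)) - clean)^2))
  })
  expect_equal(e[2] / e[1], 1 / 2, tolerance = 0.1)
  expect_equal(e[3] / e[1], 1 / sqrt(8), tolerance = 0.1)
  expect_equal(e[4] / e[1], 1 / 4, tolerance = 0.1)
  expect_identical(attr(average_shots(ph$shots, 8), "shots"), 8L)
  expect_error(average_shots(ph$shots, 17), "only 16")
  same <- replicate(3, ph$shots[[1]], simplify = FALSE)
  expect_equal(unclass(average_shots(same, 3)), unclass(ph$shots[[1]]),
               ignore_attr = TRUE)
})

test_that("averaged stacks equal the running mean of the first n shots", {
  ph <- shared_phantom()
  acc <- unclass(ph$shots[[1]])
  for (k in 2:8) acc <- acc + unclass(ph$shots[[k]])
  expect_equal(unclass(ph$averaged[["8"]]), acc / 8, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ground-truth csd ordering reflects the tissue classes", {
  ph <- shared_phantom()
  cs <- csd_map(ph$gt_params$phi, ph$roi)
  med <- function(k) stats::median(cs[ph$class_map == k], na.rm = TRUE)
  wm <- med(PHANTOM_CLASSES[["white_matter"]])
  gm <- med(PHANTOM_CLASSES[["grey_matter"]])
  ti <- med(PHANTOM_CLASSES[["tumour_infiltration"]])
  tc <- med(PHANTOM_CLASSES[["tumour_centre"]])
  expect_gt(tc, ti)
  expect_gt(ti, wm)
  expect_gt(gm, wm)
})

test_that("csd in white matter decreases monotonically with shot count", {
  ph <- shared_phantom()
  wm <- ph$class_map == PHANTOM_CLASSES[["white_matter"]]
  med <- sapply(c("1", "8", "16"), function(nm) {
    p <- scalar_params(decompose(normalise_m11(
      derive_mueller(ph$averaged[[nm]], ph$calib))))
    cs <- csd_map(p$phi, ph$roi & p$valid)
    stats::median(cs[wm], na.rm = TRUE)
  })
  expect_true(med["8"] < med["1"])
  expect_true(med["16"] < med["8"])
})

test_that("invalid phantom optics are rejected", {
  opt <- phantom_spec(h = 8, w = 8)$optics
  opt$white_matter$delta <- 200
  expect_error(phantom_spec(h = 8, w = 8, optics = opt), "delta")
  opt <- phantom_spec(h = 8, w = 8)$optics
  opt$grey_matter$d <- 1
  expect_error(phantom_spec(h = 8, w = 8, optics = opt), "d")
})
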