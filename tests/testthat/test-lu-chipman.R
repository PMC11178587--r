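test_that("canonical optical elements have their textbook forms", {
  expect_equal(make_linear_retarder(37, 0), diag(4))
  # quarter-wave plate at zero azimuth
  qw <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 1), c(0, 0, -1, 0))
  expect_equal(make_linear_retarder(0, 90), qw, tolerance = 1e-14)
  expect_equal(make_diattenuator(c(0, 0, 0)), diag(4))
  d <- make_diattenuator(c(0.3, 0, 0))
  expect_equal(d[1, 2:4], c(0.3, 0, 0))
  expect_error(make_diattenuator(c(0.8, 0.6, 0)), "< 1")
})

test_that("pure elements decompose into themselves", {
  f <- decompose(as1x1(diag(4)))
  expect_equal(f$M_D[1, 1, , ], diag(4))
  expect_equal(f$M_R[1, 1, , ], diag(4))
  expect_equal(f$M_Delta[1, 1, , ], diag(4))

  LR <- make_linear_retarder(40, 30)
  f <- decompose(as1x1(LR))
  expect_lt(max(abs(f$M_D[1, 1, , ] - diag(4))), 1e-10)
  expect_lt(max(abs(f$M_Delta[1, 1, , ] - diag(4))), 1e-10)
  expect_lt(max(abs(f$M_R[1, 1, , ] - LR)), 1e-10)

  Dep <- diag(c(1, 0.7, 0.6, 0.5))
  f <- decompose(as1x1(Dep))
  expect_lt(max(abs(f$M_D[1, 1, , ] - diag(4))), 1e-10)
  expect_lt(max(abs(f$M_R[1, 1, , ] - diag(4))), 1e-10)
  expect_lt(max(abs(f$M_Delta[1, 1, , ] - Dep)), 1e-10)
})

test_that("scalar parameters follow the closed-form identities", {
  # identity factors: no diattenuation, no depolarisation, no retardance
  p <- scalar_params(decompose(as1x1(diag(4))))
  expect_equal(p$D[1, 1], 0)
  expect_equal(p$Delta[1, 1], 0)
  expect_equal(p$R[1, 1], 0)
  expect_false(p$phi_defined[1, 1])  # azimuth undefined at sin(R) = 0

  # linear retarder: R = delta via M_R22 + M_R33 = 1 + cos(delta),
  # phi = theta via the quadrant-aware halved arctangent
  LR <- make_linear_retarder(40, 30)
  expect_equal(LR[2, 2] + LR[3, 3], 1 + cos(30 * pi / 180))
  expect_equal(LR[3, 2] - LR[2, 3], 0)
  expect_equal(LR[2, 4] / LR[4, 3], tan(2 * 40 * pi / 180))
  p <- scalar_params(decompose(as1x1(LR)))
  expect_equal(p$R[1, 1], 30, tolerance = 1e-9)
  expect_equal(p$phi[1, 1], 40, tolerance = 1e-9)

  # pure depolariser: Delta from the 3x3 submatrix trace
  p <- scalar_params(decompose(as1x1(diag(c(1, 0.7, 0.6, 0.5)))))
  expect_equal(p$Delta[1, 1], 1 - (0.7 + 0.6 + 0.5) / 3)
  # literal 4x4-trace variant
  p4 <- scalar_params(decompose(as1x1(diag(c(1, 0.7, 0.6, 0.5)))),
                      delta_trace = "full4")
  expect_equal(p4$Delta[1, 1], 1 - (1 + 0.7 + 0.6 + 0.5) / 3)

  # diattenuator round trip: D = |dvec|
  p <- scalar_params(decompose(as1x1(make_diattenuator(c(0.3, 0, 0)))))
  expect_equal(p$D[1, 1], 0.3, tolerance = 1e-12)
})

test_that("retarder grid round-trip recovers (theta, delta) to 1e-6 deg", {
  worst <- 0
  for (th in seq(0, 179, by = 3)) {
    for (dl in seq(5, 175, by = 10)) {
      p <- scalar_params(decompose(as1x1(make_linear_retarder(th, dl))))
      worst <- max(worst, abs(p$R[1, 1] - dl),
                   abs(axial_diff(p$phi[1, 1], th)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("random products reconstruct and factors are recovered", {
  set.seed(11)
  n <- 400
  recon <- 0; ferr <- 0
  for (k in seq_len(n)) {
    th <- runif(1, 0, 180); dl <- runif(1, 5, 175)
    dv <- runif(3, -0.5, 0.5)
    nd <- sqrt(sum(dv^2)); if (nd > 0.8) dv <- dv * 0.8 / nd
    ab <- runif(3, 0.3, 0.95)
    MD <- make_diattenuator(dv)
    MR <- make_linear_retarder(th, dl)
    MDel <- make_depolariser(ab)
    M <- MDel %*% MR %*% MD
    f <- decompose(as1x1(M))
    expect_true(f$valid[1, 1])
    rec <- lc_reconstruct(f)
    recon <- max(recon, max(abs(unclass(rec)[1, 1, , ] - M)))
    ferr <- max(ferr,
                max(abs(f$M_D[1, 1, , ] - MD)),
                max(abs(f$M_R[1, 1, , ] - MR)),
                max(abs(f$M_Delta[1, 1, , ] - MDel)))
  }
  expect_lt(recon, 1e-8)
  expect_lt(ferr, 1e-6)
})

test_that("retarder factor is a proper rotation and ranges hold", {
  set.seed(12)
  M <- random_mueller_image(10, 10)
  f <- decompose(M)
  p <- scalar_params(f)
  v <- f$valid
  expect_true(all(v))
  dets <- apply(which(v, arr.ind = TRUE), 1, function(ij) {
    det(f$M_R[ij[1], ij[2], 2:4, 2:4])
  })
  expect_lt(max(abs(dets - 1)), 1e-8)
  expect_true(all(p$D[v] >= 0 & p$D[v] <= 1))
  expect_true(all(p$Delta[v] >= 0 & p$Delta[v] <= 1))
  expect_true(all(p$R[v] >= 0 & p$R[v] <= 180))
  expect_true(all(p$phi[v] >= 0 & p$phi[v] < 180))
})

test_that("degenerate pixels are masked, not thrown", {
  arr <- array(0, c(1, 2, 4, 4))
  arr[1, 1, , ] <- make_linear_retarder(10, 20)
  bad <- diag(4); bad[1, 2] <- 1.2      # diattenuation >= 1
  arr[1, 2, , ] <- bad
  f <- decompose(mueller_image(arr, normalised = TRUE))
  expect_true(f$valid[1, 1])
  expect_false(f$valid[1, 2])
})

test_that("azimuth map is equivariant under scene rotation", {
  set.seed(13)
  rho <- 25
  th <- runif(16, 0, 180); dl <- runif(16, 10, 170)
  phi0 <- phi1 <- numeric(16)
  for (k in 1:16) {
    p0 <- scalar_params(decompose(as1x1(make_linear_retarder(th[k], dl[k]))))
    p1 <- scalar_params(decompose(as1x1(make_linear_retarder(th[k] + rho, dl[k]))))
    phi0[k] <- p0$phi[1, 1]; phi1[k] <- p1$phi[1, 1]
  }
  expect_lt(max(abs(axial_diff(phi1, phi0 + rho))), 1e-8)
})
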