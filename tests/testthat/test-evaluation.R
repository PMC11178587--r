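test_that("rmse matches the per-pixel loop oracle, linear and axial", {
  set.seed(21)
  x <- matrix(runif(16 * 16, 0, 180), 16)
  y <- matrix(runif(16 * 16, 0, 180), 16)
  roi <- matrix(runif(256) > 0.3, 16)
  # linear oracle
  acc <- 0; np <- 0
  for (i in 1:16) for (j in 1:16) if (roi[i, j]) {
    acc <- acc + (x[i, j] - y[i, j])^2; np <- np + 1
  }
  expect_equal(rmse(x, y, roi), sqrt(acc / np), tolerance = 1e-12)
  # axial oracle with explicit wrap
  acc <- 0
  for (i in 1:16) for (j in 1:16) if (roi[i, j]) {
    d <- (x[i, j] - y[i, j]) %% 180
    if (d > 90) d <- d - 180
    acc <- acc + d^2
  }
  expect_equal(rmse(x, y, roi, circular = TRUE), sqrt(acc / np),
               tolerance = 1e-12)
  expect_equal(rmse(x, x), 0)
  # 179 vs 1 degrees is a 2-degree axial error
  expect_equal(rmse(matrix(179), matrix(1), circular = TRUE), 2)
  expect_error(rmse(x, y, roi & FALSE), "empty ROI")
})

test_that("axial metrics are invariant to adding 180 to any subset", {
  set.seed(22)
  x <- matrix(runif(64, 0, 180), 8)
  y <- matrix(runif(64, 0, 180), 8)
  x2 <- x + 180 * (matrix(runif(64), 8) > 0.5)
  expect_equal(rmse(x2, y, circular = TRUE), rmse(x, y, circular = TRUE))
  expect_equal(csd_map(x %% 180), csd_map(x2 %% 180), tolerance = 1e-10)
})

test_that("npsnr follows its defining identities", {
  set.seed(23)
  ref <- matrix(runif(64, 0, 2), 8)
  x <- ref + matrix(rnorm(64, 0, 0.1), 8)
  e <- rmse(x, ref)
  rng <- diff(range(ref))
  expect_equal(npsnr(x, ref), 20 * log10(rng / e), tolerance = 1e-12)
  # halving the error adds 20 log10(2) dB
  x2 <- ref + (x - ref) / 2
  expect_equal(npsnr(x2, ref) - npsnr(x, ref), 20 * log10(2),
               tolerance = 1e-9)
  expect_equal(npsnr(ref, ref), Inf)
  expect_error(npsnr(x, matrix(1, 8, 8)), "zero dynamic range")
})

test_that("ssim: identity, monotone degradation, constant-shift closed form", {
  set.seed(24)
  ref <- matrix(runif(24 * 24), 24)
  expect_equal(ssim(ref, ref), 100, tolerance = 1e-9)
  s <- sapply(c(0.05, 0.2, 0.8), function(sg) {
    set.seed(100)
    ssim(ref + matrix(rnorm(24 * 24, 0, sg), 24), ref)
  })
  expect_true(all(diff(s) < 0))
  expect_true(all(s < 100))
  # constant images: only the luminance term survives
  mu_x <- 0.4; mu_y <- 0.6; L <- 1
  C1 <- (0.01 * L)^2
  got <- ssim(matrix(mu_x, 16, 16), matrix(mu_y, 16, 16), dynamic_range = L)
  expect_equal(got, 100 * (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1),
               tolerance = 1e-9)
  expect_error(ssim(matrix(0, 3, 3), matrix(0, 3, 3), window = 7), "window")
})

test_that("csd_map matches a direct per-pixel loop oracle", {
  set.seed(25)
  phi <- matrix(runif(16 * 16, 0, 180), 16)
  valid <- matrix(runif(256) > 0.2, 16)
  got <- csd_map(phi, valid, window = 5)
  for (i in c(1, 4, 9, 16)) for (j in c(2, 8, 16)) {
    ii <- max(1, i - 2):min(16, i + 2)
    jj <- max(1, j - 2):min(16, j + 2)
    ang <- 2 * phi[ii, jj][valid[ii, jj]] * pi / 180
    if (length(ang) < 3) {
      expect_true(is.na(got[i, j]))
    } else {
      rbar <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
      expect_equal(got[i, j], 0.5 * sqrt(-2 * log(rbar)) * 180 / pi,
                   tolerance = 1e-10)
    }
  }
})

test_that("csd_map handles the degenerate resultant cases", {
  expect_equal(max(csd_map(matrix(73.2, 10, 10))), 0)
  # equal counts of 0 and 90 degrees: doubled unit vectors are antipodal
  # and the resultant vanishes, so csd hits the configured cap
  phi <- matrix(0, 9, 9)
  phi[5, c(4, 6)] <- 90
  valid <- matrix(FALSE, 9, 9)
  valid[5, 3:6] <- TRUE                 # two 0s and two 90s in the window
  cs <- csd_map(phi, valid, window = 5, cap = 1e3)
  expect_equal(cs[5, 5], 1e3)
})

test_that("wilcoxon rank-sum matches brute-force enumeration", {
  # fully separated samples: 2 / choose(6, 3)
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_gte(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3)), 0.99)
  # enumeration oracle over all C(n + m, n) assignments, with ties
  oracle <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    n <- length(pooled); m <- length(a)
    w <- sum(r[seq_len(m)])
    combs <- utils::combn(n, m)
    ws <- apply(combs, 2, function(ix) sum(r[ix]))
    min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
  }
  set.seed(26)
  for (rep in 1:12) {
    a <- sample(1:8, sample(3:6, 1), replace = TRUE)  # replace => ties
    b <- sample(2:9, sample(3:6, 1), replace = TRUE)
    expect_equal(wilcoxon_ranksum(a, b), oracle(a, b), tolerance = 1e-12)
  }
  # large samples: normal approximation agrees with stats::wilcox.test
  a <- rnorm(30); b <- rnorm(30, 0.5)
  expect_equal(wilcoxon_ranksum(a, b),
               stats::wilcox.test(a, b, exact = FALSE)$p.value)
  expect_error(wilcoxon_ranksum(1:2, 1:5), "at least 3")
})

test_that("summarize_scores builds ordered quartiles and significance stars", {
  expect_equal(unname(stats::quantile(1:8, c(.25, .5, .75), type = 7)),
               c(2.75, 4.5, 6.25))
  set.seed(27)
  sc <- rbind(
    data.frame(method = "PDDN", quantity = "phi", score = rnorm(8, 10)),
    data.frame(method = "LQ", quantity = "phi", score = rnorm(8, 30)),
    data.frame(method = "GBLR", quantity = "phi", score = rnorm(8, 10.2)))
  rep <- summarize_scores(sc, reference = "PDDN")
  tb <- rep$table
  expect_true(all(tb$q1 <= tb$median & tb$median <= tb$q3))
  expect_true(tb$significant[tb$method == "LQ"])
  expect_false(tb$significant[tb$method == "GBLR"])
  expect_true(is.na(tb$p_value[tb$method == "PDDN"]))
  # single image: quartiles collapse
  one <- summarize_scores(data.frame(method = "m", quantity = "q", score = 5),
                          reference = "m")
  expect_equal(unlist(one$table[, c("q1", "median", "q3")]),
               c(q1 = 5, median = 5, q3 = 5))
  # order invariance
  rep2 <- summarize_scores(sc[sample(nrow(sc)), ], reference = "PDDN")
  o1 <- rep$table[order(rep$table$method), ]
  o2 <- rep2$table[order(rep2$table$method), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
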