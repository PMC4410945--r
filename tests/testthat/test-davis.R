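test_that("forward model examples and domain errors", {
  expect_equal(davisForward(0.3, 1, 1, davisParams(beta = 1.3)), 0)
  expect_equal(davisForward(0.05, 1.3, 1, davisParams(beta = 1.3)),
               0.05 * (1 - 1.3^(-1.1)))
  expect_equal(davisForward(0.072, 1.31, 1.175, davisParams(beta = 1.3)),
               0.006, tolerance = 0.03)
  expect_error(davisForward(-0.1, 1.3, 1, davisParams(beta = 1.3)),
               "positive")
})

test_that("isometabolic M estimation reproduces the published group means", {
  # printed group-mean responses (BOLD/GM ROI) invert to the printed M values
  expect_equal(estimateM(0.009, 1.13, davisParams(beta = 1.3)), 0.072,
               tolerance = 0.01)
  expect_equal(estimateM(0.016, 1.12, davisParams(beta = 1.0)), 0.186,
               tolerance = 0.01)
  expect_equal(estimateM(0, 1.3, davisParams(beta = 1.3)), 0)
  expect_error(estimateM(0.01, 0.99, davisParams(beta = 1.3)),
               "calibration undefined")
  expect_error(estimateM(-0.01, 1.3, davisParams(beta = 1.3)),
               "non-negative")
})

test_that("CMRO2 inversion reproduces the published group means", {
  M3 <- estimateM(0.009, 1.13, davisParams(beta = 1.3))
  expect_equal(estimateCMRO2(0.006, 1.31, M3, davisParams(beta = 1.3)),
               1.17, tolerance = 0.01)
  expect_equal(estimateCMRO2(0.013, 1.47, 0.088, davisParams(beta = 1.5)),
               1.255, tolerance = 0.005)
  # isometabolic round trip is exact
  p <- davisParams(beta = 1.3)
  expect_equal(estimateCMRO2(davisForward(0.08, 1.4, 1, p), 1.4, 0.08, p), 1)
  expect_error(estimateCMRO2(0.09, 1.3, 0.08, p), "non-physical")
})

test_that("forward and inverse are mutual identities over a dense grid", {
  for (beta in c(1.3, 1.5, 2)) {
    p <- davisParams(beta = beta)
    g <- expand.grid(f = seq(1.01, 2, length.out = 15),
                     r = seq(0.8, 1.5, length.out = 15),
                     M = seq(0.01, 0.4, length.out = 15))
    db <- davisForward(g$M, g$f, g$r, p)
    ok <- db < g$M            # inversion domain
    rBack <- estimateCMRO2(db[ok], g$f[ok], g$M[ok], p)
    expect_lt(max(abs(rBack - g$r[ok])), 1e-10)
    # inverse-then-forward on the hypercapnia branch
    Mback <- estimateM(davisForward(g$M, g$f, 1, p), g$f, p)
    expect_lt(max(abs(Mback - g$M)), 1e-10)
  }
})

test_that("closed-form CMRO2 inversion agrees with a bisection oracle", {
  set.seed(7)
  n <- 200
  for (beta in c(1.3, 1.5)) {
    p <- davisParams(beta = beta)
    M <- runif(n, 0.02, 0.3)
    f <- runif(n, 1.05, 1.9)
    r <- runif(n, 0.85, 1.4)
    db <- davisForward(M, f, r, p)
    keep <- db < M
    for (i in which(keep)[1:50]) {
      expect_equal(estimateCMRO2(db[i], f[i], M[i], p),
                   bisectCMRO2(db[i], f[i], M[i], p), tolerance = 1e-9)
    }
  }
})

test_that("CMRO2 estimate is monotone in its inputs", {
  p <- davisParams(beta = 1.3)
  db <- seq(0.001, 0.02, length.out = 20)
  expect_true(all(diff(estimateCMRO2(db, 1.3, 0.08, p)) < 0))
  f <- seq(1.05, 1.8, length.out = 20)
  expect_true(all(diff(estimateCMRO2(0.006, f, 0.08, p)) > 0))
})

test_that("echo-time scaling is linear and reproduces the published values", {
  expect_lt(abs(scaleMToOptimalTE(0.076, 17, 35) - 0.156), 0.001)
  expect_lt(abs(scaleMToOptimalTE(0.191, 17, 25) - 0.281), 0.001)
  expect_equal(scaleMToOptimalTE(0.1, 25, 25), 0.1)
  expect_error(scaleMToOptimalTE(0.1, 0, 25), "positive")
})
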