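test_that("white-noise input yields a null model with the sample covariance", {
  set.seed(11)
  x <- matrix(rnorm(2 * 50000), 2)
  fit <- fitMVAR(x, order = 1)
  expect_lt(max(abs(fit@coefficients)), 0.03)
  sampCov <- tcrossprod(x - rowMeans(x)) / (ncol(x) - 1)
  expect_lt(max(abs(fit@residualCovariance - sampCov)), 0.02)
})

test_that("generating coefficients are recovered from a simulated MVAR(2)", {
  A1 <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  A2 <- matrix(c(-0.2, 0, 0, 0.1), 2, 2)
  tpl <- MVARModel(array(c(A1, A2), c(2, 2, 2)))
  x <- generateSubjectEEG(tpl, jitter = 0, nSamples = 20000, seed = 5)
  fit <- fitMVAR(x, order = 2)
  expect_lt(max(abs(fit@coefficients - tpl@coefficients)), 0.05)
  expect_lt(max(abs(fit@residualCovariance - diag(2))), 0.05)
})

test_that("partial-correlation estimates agree with the least-squares oracle", {
  tpl <- MVARModel(array(c(0.4, 0.25, 0.1, 0.3,   # lag 1
                           -0.15, 0, 0.05, 0.1,   # lag 2
                           0.05, 0, 0, -0.05),    # lag 3
                         c(2, 2, 3)))
  x <- generateSubjectEEG(tpl, jitter = 0, nSamples = 20000, seed = 9)
  vm <- fitMVAR(x, order = 3)
  ls <- lsFitMVAR(x, 3)
  expect_lt(max(abs(vm@coefficients - ls$A)), 0.02)
  expect_lt(max(abs(vm@residualCovariance - ls$Sigma)), 0.02)
})

test_that("input validation catches bad signals and orders", {
  x <- matrix(rnorm(200), 2)
  x[1, 5] <- NA
  expect_error(fitMVAR(x, 2), "non-finite")
  expect_error(fitMVAR(matrix(rnorm(20), 2), 15), "samples")
  expect_warning(fitMVAR(matrix(rnorm(2 * 30), 2), 15), "unstable")
  # perfectly collinear channels make the error covariance singular
  z <- rnorm(5000)
  expect_error(fitMVAR(rbind(z, z), 1), "singular")
})

test_that("zero-coefficient model transforms to identity Af, H and S = Sigma", {
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  mdl <- MVARModel(array(0, c(2, 2, 1)), Sigma)
  sp <- spectralTransform(mdl, 2:80)
  expect_equal(max(abs(sp@Af - array(diag(2), c(2, 2, 79)))), 0)
  expect_equal(max(abs(sp@H - array(diag(2), c(2, 2, 79)))), 0)
  for (fi in c(1, 40, 79))
    expect_equal(Re(sp@S[, , fi]), Sigma, tolerance = 1e-12)
})

test_that("univariate AR(1) spectrum matches the closed form to 1e-10", {
  mdl <- MVARModel(array(0.5, c(1, 1, 1)), matrix(1), samplingRate = 200)
  sp <- spectralTransform(mdl, 2:80)
  f <- 2:80
  closed <- 1 / Mod(1 - 0.5 * exp(-2i * pi * f / 200))^2
  expect_lt(max(abs(Re(sp@S[1, 1, ]) - closed) / closed), 1e-10)
  # and the AR polynomial modulus itself
  afMod <- Mod(sp@Af[1, 1, ])
  expect_lt(max(abs(afMod - Mod(1 - 0.5 * exp(-2i * pi * f / 200)))), 1e-12)
})

test_that("Af(f) H(f) = I on every grid point of a fitted model", {
  set.seed(3)
  x <- matrix(rnorm(3 * 4000), 3)
  sp <- spectralTransform(fitMVAR(x, 4), 2:80)
  dev <- vapply(seq_len(79), function(fi)
    max(Mod(sp@Af[, , fi] %*% sp@H[, , fi] - diag(3))), 0)
  expect_lt(max(dev), 1e-8)
  # S Hermitian with real non-negative diagonal
  herm <- vapply(seq_len(79), function(fi)
    max(Mod(sp@S[, , fi] - Conj(t(sp@S[, , fi])))), 0)
  expect_lt(max(herm), 1e-10)
  expect_true(all(vapply(seq_len(79), function(fi)
    all(Re(diag(sp@S[, , fi])) >= 0), TRUE)))
})

test_that("rescaling the signal scales Sigma and S by c^2, coefficients unchanged", {
  tpl <- unidirTemplate()
  x <- generateSubjectEEG(tpl, 0, 8000, seed = 21)
  f1 <- fitMVAR(x, 1)
  f2 <- fitMVAR(3 * x, 1)
  expect_equal(f1@coefficients, f2@coefficients, tolerance = 1e-10)
  expect_equal(9 * f1@residualCovariance, f2@residualCovariance,
               tolerance = 1e-8)
  s1 <- spectralTransform(f1, 2:80)
  s2 <- spectralTransform(f2, 2:80)
  expect_equal(9 * s1@S, s2@S, tolerance = 1e-6)
})

test_that("estimated models on stable synthetic data are almost always stable", {
  tpl <- unidirTemplate()
  unstable <- 0
  for (s in 1:20) {
    x <- generateSubjectEEG(tpl, 0, 3000, seed = 100 + s)
    if (!isStable(fitMVAR(x, 1))) unstable <- unstable + 1
  }
  expect_lte(unstable, 1)
})

test_that("frequency-grid validation and JSON round trip work", {
  mdl <- unidirTemplate()
  expect_error(spectralTransform(mdl, c(0, 10)), "frequencies")
  expect_error(spectralTransform(mdl, 150), "frequencies")
  js <- mvarToJSON(mdl)
  back <- mvarFromJSON(js)
  expect_equal(back@coefficients, mdl@coefficients, tolerance = 1e-12)
  expect_equal(back@residualCovariance, mdl@residualCovariance,
               tolerance = 1e-12)
  expect_identical(back@channelLabels, mdl@channelLabels)
})
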