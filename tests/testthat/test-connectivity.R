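# shared small fitted model for identity checks
fittedSpec <- local({
  tpl <- unidirTemplate()
  x <- generateSubjectEEG(tpl, 0, 6000, seed = 31)
  mdl <- fitMVAR(x, 2)
  spectralTransform(mdl, 2:80)
})

test_that("self-coherence is exactly 1 and independence gives zero coherence", {
  coh <- coherencyFamily(fittedSpec)
  for (fi in c(1, 30, 79)) {
    expect_equal(diag(coh$COH@values[, , fi]), c(1, 1), tolerance = 1e-12)
  }
  # zero-coefficient model with diagonal Sigma: strict independence
  nullSpec <- spectralTransform(MVARModel(array(0, c(2, 2, 1)), diag(c(2, 3))),
                                2:80)
  cohN <- coherencyFamily(nullSpec)
  expect_equal(max(abs(cohN$COH@values[1, 2, ])), 0)
  expect_equal(max(abs(cohN$iCOH@values)), 0)
  expect_equal(max(abs(cohN$pCOH@values[1, 2, ])), 0)
})

test_that("MVAR coherence agrees with a nonparametric Welch-type estimate", {
  tpl <- MVARModel(array(c(0.6, 0.5, 0, 0.5), c(2, 2, 1)))
  x <- generateSubjectEEG(tpl, 0, 50000, seed = 41)
  mdl <- fitMVAR(x, 4)
  coh <- coherencyFamily(spectralTransform(mdl, 2:80))$COH@values
  pg <- stats::spec.pgram(stats::ts(t(x), frequency = 200),
                          spans = c(51, 51), taper = 0, plot = FALSE,
                          detrend = FALSE)
  # compare at the frequency of maximal model coherence
  fPeak <- which.max(coh[2, 1, ]) + 1       # grid starts at 2 Hz
  pgIdx <- which.min(abs(pg$freq - fPeak))
  welch <- sqrt(pg$coh[pgIdx])
  expect_lt(abs(coh[2, 1, fPeak - 1] - welch), 0.1)
})

test_that("PDC satisfies its column normalization and structural zeros", {
  pdc <- pdcFamily(fittedSpec)$PDC@values
  colnorm <- apply(pdc^2, c(2, 3), sum)
  expect_lt(max(abs(colnorm - 1)), 1e-10)
  # zero-coefficient model: PDC = identity pattern
  nullSpec <- spectralTransform(MVARModel(array(0, c(2, 2, 1))), 2:80)
  pdcN <- pdcFamily(nullSpec)$PDC@values
  expect_equal(pdcN[1, 1, ], rep(1, 79))
  expect_equal(max(abs(pdcN[1, 2, ])), 0)
  # unidirectional analytic model: influence 2 -> 1 is exactly zero
  uni <- spectralTransform(unidirTemplate(), 2:80)
  pdcU <- pdcFamily(uni)$PDC@values
  dcU <- grangerFamily(uni)$DC@values
  expect_equal(max(abs(pdcU[1, 2, ])), 0)     # source 2 -> sink 1 absent
  expect_gt(max(pdcU[2, 1, ]), 0.1)           # source 1 -> sink 2 present
  expect_equal(max(abs(dcU[1, 2, ])), 0)
  expect_gt(max(dcU[2, 1, ]), 0.1)
})

test_that("PDCF and GPDC follow their stated denominators", {
  sp <- fittedSpec
  Sigma <- sp@residualCovariance
  SigInv <- solve(Sigma)
  fi <- 17
  A <- sp@Af[, , fi]
  pf <- pdcFamily(sp)
  for (j in 1:2) {
    aj <- A[, j]
    denPDCF <- sqrt(Re(Conj(aj) %*% SigInv %*% aj))
    expect_equal(pf$PDCF@values[, j, fi], unname(Mod(A[, j]) / drop(denPDCF)),
                 tolerance = 1e-12)
    denG <- sqrt(sum(Mod(A[, j])^2 / diag(Sigma)))
    expect_equal(pf$GPDC@values[, j, fi],
                 unname((Mod(A[, j]) / sqrt(diag(Sigma))) / denG),
                 tolerance = 1e-12)
  }
})

test_that("DTF row and ffDTF full-frequency normalizations hold", {
  fam <- dtfFamily(fittedSpec)
  rownorm <- apply(fam$DTF@values^2, c(1, 3), sum)
  expect_lt(max(abs(rownorm - 1)), 1e-10)
  total <- apply(fam$ffDTF@values^2, 1, sum)
  expect_lt(max(abs(total - 1)), 1e-10)
  # dDTF is the product of ffDTF and partial coherence
  pcoh <- coherencyFamily(fittedSpec)$pCOH@values
  expect_equal(fam$dDTF@values, fam$ffDTF@values * pcoh, tolerance = 1e-12)
  # zero-coefficient model: DTF identity pattern
  nullSpec <- spectralTransform(MVARModel(array(0, c(2, 2, 1))), 2:80)
  dtfN <- dtfFamily(nullSpec)$DTF@values
  expect_equal(dtfN[1, 1, ], rep(1, 79))
  expect_equal(max(abs(dtfN[1, 2, ])), 0)
})

test_that("GGC matches its analytic closed form and is non-negative", {
  # pure coupling model: A1[2,1] = 0.4, Sigma = I
  tpl <- MVARModel(array(c(0, 0.4, 0, 0), c(2, 2, 1)))
  sp <- spectralTransform(tpl, 2:80)
  ggc <- grangerFamily(sp)$GGC@values
  # by hand: H = [[1, 0], [0.4 z, 1]], S22 = 1 + 0.16, GGC(2<-1) = ln(1.16)
  expect_equal(ggc[2, 1, ], rep(log(1.16), 79), tolerance = 1e-8)
  expect_equal(max(abs(ggc[1, 2, ])), 0)
  expect_true(all(grangerFamily(fittedSpec)$GGC@values >= 0))
  # independent channels: no causality anywhere
  ind <- spectralTransform(MVARModel(array(c(0.5, 0, 0, 0.3), c(2, 2, 1)),
                                     diag(c(1, 2))), 2:80)
  gI <- grangerFamily(ind)
  expect_equal(max(abs(gI$GGC@values[1, 2, ])), 0)
  expect_equal(max(abs(gI$GGC@values[2, 1, ])), 0)
  expect_equal(max(abs(gI$DC@values[1, 2, ])), 0)
})

test_that("raw family returns the moduli of S, H and Af", {
  raw <- rawFamily(fittedSpec)
  expect_equal(raw$S@values, Mod(fittedSpec@S), tolerance = 1e-15)
  expect_equal(raw$h@values, Mod(fittedSpec@H), tolerance = 1e-15)
  expect_equal(raw$Af@values, Mod(fittedSpec@Af), tolerance = 1e-15)
  # white-noise model: h is the identity pattern at every frequency
  nullSpec <- spectralTransform(MVARModel(array(0, c(2, 2, 1))), 2:80)
  hN <- rawFamily(nullSpec)$h@values
  expect_equal(hN[1, 1, ], rep(1, 79))
  expect_equal(max(abs(hN[2, 1, ])), 0)
})

test_that("band averaging uses exactly the canonical integer bands", {
  m <- 2
  vals <- array(0, c(m, m, 79))
  for (fi in 1:79) vals[, , fi] <- fi + 1   # value = frequency
  ten <- eegspect:::ConnectivityArray("COH", 2:80, vals)
  ba <- bandAverage(ten)
  expect_equal(ba@values[1, 1, "delta"], mean(2:4))
  expect_equal(ba@values[1, 1, "theta"], mean(5:7))
  expect_equal(ba@values[1, 1, "alpha"], mean(8:13))
  expect_equal(ba@values[1, 1, "beta"], mean(14:30))
  expect_equal(ba@values[1, 1, "gamma"], mean(31:80))
  # constant tensor: every band equals the constant
  cvals <- array(0.7, c(m, m, 79))
  bc <- bandAverage(eegspect:::ConnectivityArray("COH", 2:80, cvals))
  expect_true(all(bc@values == 0.7))
  expect_error(bandAverage(eegspect:::ConnectivityArray("COH", 2:40,
                                                        cvals[, , 1:39])),
               "grid")
})

test_that("computeAllMeasures yields 14 banded tensors with bounded ranges", {
  tpl <- unidirTemplate()
  x <- generateSubjectEEG(tpl, 0, 4000, seed = 55)
  mdl <- fitMVAR(x, 2)
  all14 <- computeAllMeasures(mdl)
  expect_identical(names(all14), connectivityMeasures())
  for (nm in c("COH", "PDC", "GPDC", "DTF")) {
    v <- all14[[nm]]@values
    expect_true(all(v >= -1e-12 & v <= 1 + 1e-12), info = nm)
  }
  expect_true(all(abs(all14$iCOH@values) <= 1 + 1e-12))
  expect_identical(dim(all14$PDC@values), c(2L, 2L, 5L))
  # deterministic
  again <- computeAllMeasures(mdl)
  expect_identical(all14$GGC@values, again$GGC@values)
})

test_that("normalized measures are invariant to signal rescaling", {
  tpl <- unidirTemplate()
  x <- generateSubjectEEG(tpl, 0, 6000, seed = 66)
  a <- computeAllMeasures(fitMVAR(x, 2))
  # uniform rescaling leaves the whole normalized family unchanged
  b <- computeAllMeasures(fitMVAR(2.5 * x, 2))
  for (nm in c("COH", "iCOH", "pCOH", "PDC", "GPDC", "DTF", "ffDTF", "dDTF")) {
    expect_equal(a[[nm]]@values, b[[nm]]@values, tolerance = 1e-6, info = nm)
  }
  # per-channel rescaling: only the variance-normalized measures are
  # invariant (plain PDC/DTF are scale-variant by construction, which is
  # the textbook motivation for GPDC)
  d <- computeAllMeasures(fitMVAR(diag(c(5, 0.2)) %*% x, 2))
  for (nm in c("COH", "iCOH", "pCOH", "GPDC")) {
    expect_equal(a[[nm]]@values, d[[nm]]@values, tolerance = 1e-6, info = nm)
  }
  expect_gt(max(abs(a$PDC@values - d$PDC@values)), 0.01)
})

test_that("long-format export carries full provenance per value", {
  tpl <- unidirTemplate()
  banded <- computeAllMeasures(fitMVAR(generateSubjectEEG(tpl, 0, 3000, 77), 2))
  long <- bandedToLong(banded, "subj1")
  expect_equal(nrow(long), 14 * 5 * 4)
  expect_setequal(unique(long$measure), connectivityMeasures())
  # orientation: value for (sink, source) matches the array entry
  row <- long[long$measure == "PDC" & long$band == "delta" &
                long$source == "ch1" & long$sink == "ch2", ]
  expect_equal(row$value, banded$PDC@values[2, 1, "delta"])
})
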