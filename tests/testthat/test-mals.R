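test_that("weight-fraction mixing reproduces the printed optical constants", {
  cmp <- malsComponents()
  # dn/dc: 0.185*0.877 + 0.145*0.123 = 0.18008, printed as 0.181
  expect_equal(mixDndc(cmp$prot, cmp$glyc, cmp$f), 0.18008,
               tolerance = 1e-12)
  expect_lt(abs(mixDndc(cmp$prot, cmp$glyc, cmp$f) - 0.181), 0.001)
  # extinction: 1.411*0.877 + 0*0.123 = 1.2374, printed as 1.237
  expect_lt(abs(mixExtinction(cmp$prot, cmp$glyc, cmp$f) - 1.237), 0.001)
  # identities and bounds
  expect_equal(mixDndc(cmp$prot, cmp$glyc, weightFractions(1)), 0.185)
  expect_equal(mixExtinction(cmp$prot, cmp$glyc, weightFractions(1)), 1.411)
  expect_equal(mixExtinction(cmp$prot, cmp$glyc, weightFractions(0)), 0)
  same <- opticalComponent("x", 0.17, 1)
  expect_equal(mixDndc(same, same, weightFractions(0.31)), 0.17)
  set.seed(4)
  for (fp in runif(10)) {
    f <- weightFractions(fp)
    m <- mixDndc(cmp$prot, cmp$glyc, f)
    expect_gte(m, min(0.185, 0.145))
    expect_lte(m, max(0.185, 0.145))
  }
})

test_that("weight fractions validate and derive from masses", {
  expect_error(weightFractions(0.6, 0.6), "sum to 1")
  expect_equal(fractionsFromMasses(5, 5)@fProt, 0.5)
  f <- fractionsFromMasses(0.877 * 62100, 0.123 * 62100)
  expect_equal(f@fProt, 0.877, tolerance = 1e-12)
  expect_equal(f@fProt + f@fGlycan, 1)
  expect_error(fractionsFromMasses(0, 0), "positive")
})

test_that("slice solving inverts the forward model exactly", {
  cmp <- malsComponents()
  cc <- 0.5; cm <- 0.2; M <- 272970
  dndcW <- (cmp$conj@dndc * cc + cmp$ddm@dndc * cm) / (cc + cm)
  ch <- malsChromatogram(
    volume = 12,
    ls = M * dndcW^2 * (cc + cm),
    uv = cmp$conj@epsilon * cc,
    ri = cmp$conj@dndc * cc + cmp$ddm@dndc * cm)
  sol <- solveSlices(ch, cmp$conj, cmp$ddm)
  expect_equal(sol$cConjugate, cc, tolerance = 1e-9)
  expect_equal(sol$cModifier, cm, tolerance = 1e-9)
  expect_equal(sol$mTotal, M, tolerance = 1e-9 * M)
  # mass additivity
  expect_equal(sol$mConjugate + sol$mModifier, sol$mTotal,
               tolerance = 1e-6 * M)
  # with non-unit calibration constants
  k <- list(kLS = 2.3e-5, kUV = 0.87, kRI = 1.4e-4)
  ch2 <- malsChromatogram(12, k$kLS * M * dndcW^2 * (cc + cm),
                          k$kUV * cmp$conj@epsilon * cc,
                          k$kRI * (cmp$conj@dndc * cc + cmp$ddm@dndc * cm),
                          calibration = k)
  sol2 <- solveSlices(ch2, cmp$conj, cmp$ddm)
  expect_equal(sol2$mTotal, M, tolerance = 1e-9 * M)
})

test_that("modifier-free slices reduce to the single-component closed form", {
  cmp <- malsComponents()
  cc <- 0.8; M <- 62100
  ch <- malsChromatogram(10, M * cmp$conj@dndc^2 * cc,
                         cmp$conj@epsilon * cc, cmp$conj@dndc * cc)
  sol <- solveSlices(ch, cmp$conj, cmp$ddm)
  expect_equal(sol$cModifier, 0, tolerance = 1e-12)
  expect_equal(sol$mTotal, ch@slices$ls / (cmp$conj@dndc^2 * cc),
               tolerance = 1e-9 * M)
})

test_that("inconsistent detector signals are rejected", {
  cmp <- malsComponents()
  # UV implies far more RI than measured
  ch <- malsChromatogram(10, 1, uv = 1.411 * 0.5, ri = 0.01)
  expect_error(solveSlices(ch, cmp$conj, cmp$ddm), "inconsistent")
  # zero concentration but nonzero light scattering
  ch2 <- malsChromatogram(10, ls = 5, uv = 0, ri = 0)
  expect_error(solveSlices(ch2, cmp$conj, cmp$ddm), "zero solved")
})

test_that("peak averaging recovers uniform and simulated trimer masses", {
  cmp <- malsComponents()
  # uniform slices: peak mass equals the slice mass
  cc <- 0.4; cm <- 0.16; M <- 262070
  dndcW <- (cmp$conj@dndc * cc + cmp$ddm@dndc * cm) / (cc + cm)
  ch <- malsChromatogram(volume = 1:5,
                         ls = rep(M * dndcW^2 * (cc + cm), 5),
                         uv = rep(cmp$conj@epsilon * cc, 5),
                         ri = rep(cmp$conj@dndc * cc + cmp$ddm@dndc * cm, 5))
  pk <- peakMasses(solveSlices(ch, cmp$conj, cmp$ddm))
  expect_equal(mwConjugate(pk), M * cc / (cc + cm), tolerance = 1e-9)
  expect_equal(mwModifier(pk), M * cm / (cc + cm), tolerance = 1e-9)
  expect_equal(pk@fConjugate, cc / (cc + cm), tolerance = 1e-12)
  # simulated trimer peak with 1% seeded noise: recovery within 2%
  chrom <- genChromatogram(cmp$conj, cmp$ddm, noiseFrac = 0.01, seed = 42)
  sol <- solveSlices(chrom, cmp$conj, cmp$ddm, clampTol = 0.05, lsTol = 500)
  pk2 <- peakMasses(sol, peakRange = c(12, 13))
  expect_equal(mwConjugate(pk2), 186300, tolerance = 0.02)
  expect_equal(mwModifier(pk2), 75770, tolerance = 0.02)
  expect_error(peakMasses(sol, peakRange = c(50, 51)), "at least 3")
  # recovered trimer glycoprotein is ~3x the 62,100 Da monomer
  expect_equal(mwConjugate(pk2) / 62100, 3, tolerance = 0.05)
})
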