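mkState2 <- function(f, p01R, p11R, rs = 0.5, p01A = 0, p11A = 0)
  selfEstab:::newCohortState(f, rep_len(p01A, length(f)),
                             rep_len(p11A, length(f)),
                             rep_len(p01R, length(f)),
                             rep_len(p11R, length(f)), rs)

test_that("pairwise ID matches hand evaluation of the cohort-variance form", {
  st <- mkState2(c(0.5, 0.5), p01R = c(0.2, 0), p11R = c(0, 0.2))
  # pooled p = 0.15; ID = 0.25 * 0.2^2 / (0.15^2 * 0.85^2)
  expect_equal(pairwiseIdentityDisequilibrium(st, "RR"),
               0.25 * 0.04 / (0.15^2 * 0.85^2), tolerance = 1e-12)
  expect_equal(pairwiseIdentityDisequilibrium(st, "RR"), 0.6152,
               tolerance = 1e-4)

  # a single cohort gives ID = 0; identical cohorts give ID = 0
  one <- mkState2(c(1, 0), p01R = c(0.2, 0), p11R = c(0.1, 0), rs = 0)
  expect_equal(pairwiseIdentityDisequilibrium(one, "RR"), 0)
  same <- mkState2(c(0.4, 0.6), p01R = 0.2, p11R = 0.1)
  expect_equal(pairwiseIdentityDisequilibrium(same, "RR"), 0)

  # monomorphic type is undefined
  mono <- mkState2(c(0.5, 0.5), p01R = 0, p11R = 0)
  expect_true(is.na(pairwiseIdentityDisequilibrium(mono, "RR")))
})

test_that("summaries: delta from homozygosity differences, NA at rs = 0", {
  arch <- archRec(LR = 20, s = 0.05, h = 0.1)
  reg <- sourceRegime(arch)
  # identical frequencies with p01 = 0 everywhere: Wself = Woc, delta = 0
  st <- mkState2(c(0.6, 0.4), p01R = 0, p11R = 0.1)
  sm <- populationSummaries(st, arch, reg)
  expect_equal(unname(sm@values["delta"]), 0)
  # single cohort (rs = 0): Wbar = wbar_0 and delta is absent
  st0 <- mkState2(c(1, 0), p01R = c(0.2, 0), p11R = c(0.1, 0), rs = 0)
  sm0 <- populationSummaries(st0, arch, reg)
  nu <- 0.7 + 0.2 * exp(-0.005) + 0.1 * exp(-0.05)
  expect_equal(unname(sm0@values["meanFitness"]), nu^20)
  expect_true(is.na(sm0@values["delta"]))
})

test_that("neutral ID reference vanishes at the extremes, peaks between", {
  expect_equal(neutralIDReference(0), 0)
  expect_equal(neutralIDReference(1), 0)
  expect_lt(neutralIDReference(0.999), 0.01)
  grid <- seq(0.05, 0.95, by = 0.05)
  v <- neutralIDReference(grid)
  expect_true(all(v > 0))
  pk <- which.max(v)
  expect_true(pk > 1 && pk < length(grid))
  # matches the s = 0 limit of the cohort recursion with selection machinery
  arch <- architectureParams(LA = 0, LR = 10, muR = 1e-3, s = 0, h = 0)
  for (rs in c(0.3, 0.7)) {
    eq <- ilecEquilibrium(arch, sourceRegime(arch), rs)
    expect_equal(pairwiseIdentityDisequilibrium(eq, "RR"),
                 neutralIDReference(rs), tolerance = 0.02)
  }
})

test_that("selection depresses ID below the neutral expectation", {
  arch <- architectureParams(LA = 1000, LR = 5000, muA = 1e-4, muR = 1e-4,
                             s = 0.05, h = 0.1, s0Tilde = 0.005)
  reg <- sourceRegime(arch)
  for (rs in c(0.3, 0.5, 0.7)) {
    sm <- populationSummaries(ilecEquilibrium(arch, reg, rs), arch, reg)
    neutral <- neutralIDReference(rs)
    for (q in c("idAA", "idRR", "idAR"))
      expect_lt(unname(sm@values[q]), neutral)
    # ID is largely insensitive to the locus types involved
    expect_lt(diff(range(sm@values[c("idAA", "idRR", "idAR")])),
              0.15 * max(sm@values[c("idAA", "idRR", "idAR")]))
  }
})

test_that("load distribution: one-locus pmf and exact mixture moments", {
  arch <- architectureParams(LA = 0, LR = 1, muR = 0, s = 0.05, h = 0.1)
  reg <- sourceRegime(arch)
  st <- mkState2(c(1, 0), p01R = c(0.2, 0), p11R = c(0.1, 0), rs = 0)
  ld <- loadDistribution(st, arch, reg)
  on <- ld[ld$prob > 1e-9, ]
  expect_equal(on$G, c(0, 0.005, 0.05))
  expect_equal(on$prob, c(0.7, 0.2, 0.1), tolerance = 1e-9)

  # mixture mean is exact; the log-cohort-fitness sum agrees to O(s)
  arch2 <- archBoth(LA = 50, LR = 200, s = 0.05, h = 0.1, s0 = 0.005)
  reg2 <- sourceRegime(arch2)
  eq <- ilecEquilibrium(arch2, reg2, 0.5)
  ld2 <- loadDistribution(eq, arch2, reg2)
  expect_equal(sum(ld2$G * ld2$prob), expectedLoad(eq, arch2, reg2),
               tolerance = 1e-8)
  lw <- -sum(eq@f * selfEstab:::cohortLogMeanFitness(eq, arch2, reg2))
  expect_equal(sum(ld2$G * ld2$prob), lw, tolerance = 0.05)

  # Monte-Carlo fallback agrees with the exact mixture
  set.seed(3)
  mc <- loadDistribution(eq, arch2, reg2, method = "mc", nDraws = 2e5)
  expect_equal(sum(mc$G * mc$prob), expectedLoad(eq, arch2, reg2),
               tolerance = 0.02)
})

test_that("load distribution is bimodal under highly recessive interference", {
  arch <- architectureParams(LA = 1000, LR = 5000, muA = 1e-4, muR = 1e-4,
                             s = 0.05, h = 0.02, s0Tilde = 0.005)
  reg <- sourceRegime(arch)
  for (rs in c(0.2, 0.5, 0.8)) {
    eq <- ilecEquilibrium(arch, reg, rs)
    ld <- loadDistribution(eq, arch, reg, resolution = 0.1)
    modeOut <- ld$G[which.max(ld$probOutcrossed)]
    modeSelf <- ld$G[which.max(ld$probSelfed)]
    expect_lt(modeOut, modeSelf)  # outcrossed peak sits at lower load
    # a genuine dip separates the two peaks in the pooled density
    between <- ld$G > modeOut & ld$G < modeSelf
    expect_true(any(between))
    dip <- min(ld$prob[between])
    peakOut <- ld$prob[which.max(ld$probOutcrossed)]
    peakSelf <- ld$prob[which.max(ld$probSelfed)]
    expect_lt(dip, 0.8 * min(peakOut, peakSelf))
  }
})

test_that("population fitness is minimum at intermediate selfing (h = 0.02)", {
  arch <- architectureParams(LA = 1000, LR = 5000, muA = 1e-4, muR = 1e-4,
                             s = 0.05, h = 0.02, s0Tilde = 0.005)
  reg <- sourceRegime(arch)
  rsGrid <- seq(0, 0.9, by = 0.1)
  W <- vapply(rsGrid, function(rs)
    meanFitness(ilecEquilibrium(arch, reg, rs), arch, reg), numeric(1))
  k <- which.min(W)
  expect_true(k > 1 && k < length(rsGrid))
})
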