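# converged state constructor for hand-built founder distributions
handState <- function(f, p01R = 0, p11R = 0, p01A = 0, p11A = 0, rs = 0.5) {
  n <- length(f)
  selfEstab:::newCohortState(f, rep_len(p01A, n), rep_len(p11A, n),
                             rep_len(p01R, n), rep_len(p11R, n), rs,
                             converged = TRUE)
}

test_that("founder sampling follows cohort masses and genotype frequencies", {
  arch <- archRec(LR = 20, muR = 1e-3, s = 0.02, h = 0.1)
  # rs = 0 equilibrium: every founder has selfing age 0
  eq0 <- ilecEquilibrium(arch, sourceRegime(arch), 0)
  set.seed(4)
  f0 <- sampleFounders(eq0, arch, 50)
  expect_true(all(f0@selfingAge == 0L))

  # expected founder allele frequency equals the mixture frequency
  eq <- ilecEquilibrium(arch, sourceRegime(arch), 0.7)
  pExp <- alleleFrequency(eq)[["R"]]
  set.seed(9)
  fd <- sampleFounders(eq, arch, 10000)
  pObs <- alleleFrequency(fd, arch)[["R"]]
  se <- sqrt(pExp * (1 - pExp) / (2 * 10000 * 20))
  expect_lt(abs(pObs - pExp), 4 * se)

  # fixed seed gives an identical founder set
  set.seed(77); a <- sampleFounders(eq, arch, 12)
  set.seed(77); b <- sampleFounders(eq, arch, 12)
  expect_identical(a@hap1, b@hap1)
  expect_identical(a@selfingAge, b@selfingAge)
})

test_that("demographic update is Ricker-Poisson with absorbing extinction", {
  arch <- archAdd(LA = 10)
  isl <- islandParams(arch, rs = 0, s1Tilde = 0.01, r0 = 1.1, K = 500)
  expect_identical(demographicUpdate(0, 1, isl), 0L)
  set.seed(10)
  draws <- replicate(3000, demographicUpdate(500, 1, isl))
  expect_lt(abs(mean(draws) - 500), 4 * sqrt(500 / 3000))  # e^0 factor at K
  # far below K the per-capita mean growth factor is e^{r0} * wbar
  draws2 <- replicate(3000, demographicUpdate(5, 0.5, isl))
  m <- 5 * exp(1.1 * (1 - 5 / 500)) * 0.5
  expect_lt(abs(mean(draws2) - m), 4 * sqrt(m / 3000))
})

test_that("branching-process extinction probabilities match fixed points", {
  # m = 2: q solves q = e^{2(q-1)} ~ 0.2032, so Pest ~ 0.7968 for one line
  m2w <- 2 / exp(1.1)
  expect_equal(branchingProcessPest(m2w, 1.1), 1 - 0.20319, tolerance = 1e-4)
  # subcritical lines are doomed
  expect_equal(branchingProcessPest(0.9 / exp(1.1), 1.1), 0)
  expect_equal(branchingProcessPest(rep(0.2, 4), 0), 0)
  # N0 independent lines: 1 - q^N0, increasing in N0
  p1 <- branchingProcessPest(m2w, 1.1, N0 = 1)
  p5 <- branchingProcessPest(m2w, 1.1, N0 = 5)
  expect_equal(p5, 1 - (1 - p1)^5, tolerance = 1e-10)
  expect_equal(branchingProcessPest(rep(m2w, 5), 1.1), p5, tolerance = 1e-10)
  ps <- vapply(1:6, function(n) branchingProcessPest(m2w, 1.1, N0 = n),
               numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("perfectly adapted founders almost always establish", {
  arch <- archAdd(LA = 30, muA = 1e-4, s0 = 0.005)
  ones <- makePopulation(matrix(1, 30, 10), matrix(1, 30, 10))
  isl <- islandParams(arch, rs = 0, s1Tilde = 0.005, r0 = 1.1, K = 500,
                      N0 = 10, Tgen = 60)
  set.seed(14)
  ok <- replicate(40, establishmentReplicate(ones, arch, isl)$success)
  expect_gt(mean(ok), 0.9)
})

test_that("zero-fitness founders go extinct at first reproduction", {
  arch <- architectureParams(LA = 0, LR = 10, muR = 0, s = 800, h = 0.4)
  dead <- makePopulation(matrix(1, 10, 5), matrix(1, 10, 5))
  isl <- islandParams(arch, rs = 0.5, s1Tilde = NULL, r0 = 1.1, K = 500,
                      N0 = 5, Tgen = 50)
  set.seed(15)
  res <- establishmentReplicate(dead, arch, isl)
  expect_false(res$success)
  expect_equal(res$extinctGen, 1L)
  expect_equal(res$N[2], 0L)
})

test_that("a lone rs = 0 founder still reproduces via realized selfing", {
  arch <- archAdd(LA = 10, muA = 0, s0 = 0.001)
  one <- makePopulation(matrix(1, 10, 1), matrix(1, 10, 1))
  isl <- islandParams(arch, rs = 0, s1Tilde = 0.001, r0 = 1.1, K = 1e6,
                      N0 = 1, Tgen = 3)
  set.seed(16)
  grew <- replicate(60, {
    r <- establishmentReplicate(one, arch, isl)
    !is.na(r$N[2]) && r$N[2] > 0
  })
  # offspring number is Poisson(~e^{1.1}), so P(none) ~ e^{-3}
  expect_gt(mean(grew), 0.85)
})

test_that("establishment estimates are seed-deterministic with binomial SE", {
  arch <- archBoth(LA = 20, LR = 30, muA = 1e-3, muR = 1e-3, s = 0.05,
                   h = 0.1, s0 = 0.005)
  eq <- ilecEquilibrium(arch, sourceRegime(arch), 0.5)
  isl <- islandParams(arch, rs = 0.5, s1Tilde = 0.02, r0 = 1.1, K = 200,
                      N0 = 5, Tgen = 30)
  a <- estimateEstablishmentProbability(eq, arch, isl, R = 30, seed = 42)
  b <- estimateEstablishmentProbability(eq, arch, isl, R = 30, seed = 42)
  expect_identical(a@success, b@success)
  expect_equal(a@se, sqrt(a@pEst * (1 - a@pEst) / 30))
  expect_true(a@pEst >= 0 && a@pEst <= 1)
})

test_that("viability check accepts fit sources and rejects lethal ones", {
  archFit <- architectureParams(LA = 0, LR = 5, muR = 0, s = 0.05, h = 0.1)
  fit <- handState(c(1, 0), rs = 0)
  set.seed(18)
  v <- viabilityCheck(fit, archFit, rs = 0, replicates = 20)
  expect_true(v$viable)
  expect_equal(v$fraction, 1)

  archDead <- architectureParams(LA = 0, LR = 5, muR = 0, s = 800, h = 0.4)
  doomed <- handState(c(0, 1), p11R = 1, rs = 1)
  v2 <- viabilityCheck(doomed, archDead, rs = 1, replicates = 5)
  expect_false(v2$viable)
  expect_equal(v2$fraction, 0)
})

test_that("adaptive-allele SFS keeps fixed classes and counts all loci", {
  arch <- archAdd(LA = 8)
  allFixed <- makePopulation(matrix(1, 8, 6), matrix(1, 8, 6))
  sfs1 <- adaptiveAlleleSFS(allFixed, arch)
  expect_equal(sfs1$count[nrow(sfs1)], 8)
  expect_equal(sum(sfs1$count), 8)
  none <- makePopulation(matrix(0, 8, 6), matrix(0, 8, 6))
  sfs0 <- adaptiveAlleleSFS(none, arch)
  expect_equal(sfs0$count[1], 8)
  # numeric frequency input with interior polymorphism
  sfsV <- adaptiveAlleleSFS(c(0, 0.05, 0.5, 1, 1), bins = 4)
  expect_equal(sfsV$count, c(1, 1, 1, 0, 0, 2))
})
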