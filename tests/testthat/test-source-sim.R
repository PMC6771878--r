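test_that("initialization draws alleles at the requested frequency", {
  arch <- archBoth(LA = 20, LR = 40)
  p0 <- initializePopulation(10, arch, initFreq = 0)
  expect_true(all(p0@hap1 == as.raw(0)) && all(p0@hap2 == as.raw(0)))
  p1 <- initializePopulation(10, arch, initFreq = 1)
  expect_true(all(p1@hap1 == as.raw(1)) && all(p1@hap2 == as.raw(1)))

  set.seed(1)
  N <- 400
  ph <- initializePopulation(N, arch, initFreq = 0.5)
  nDraw <- 2 * N * 60
  se <- sqrt(0.25 / nDraw)
  obs <- (sum(ph@hap1 == as.raw(1)) + sum(ph@hap2 == as.raw(1))) / nDraw
  expect_lt(abs(obs - 0.5), 4 * se)
})

test_that("trajectories are seed-deterministic", {
  arch <- archBoth(LA = 10, LR = 20)
  reg <- sourceRegime(arch)
  run <- function() {
    set.seed(99)
    pop <- initializePopulation(50, arch, initFreq = 0.3)
    generationStep(pop, arch, reg, rs = 0.4, nGen = 25)
  }
  a <- run(); b <- run()
  expect_identical(a@hap1, b@hap1)
  expect_identical(a@hap2, b@hap2)
  expect_identical(a@selfingAge, b@selfingAge)
})

test_that("rs = 1 makes every offspring a selfed single-parent product", {
  # two maximally distinct parents; mu = 0 so no mixing is possible
  arch <- architectureParams(LA = 0, LR = 30, muR = 0, s = 0, h = 0)
  pop <- makePopulation(cbind(rep(0, 30), rep(1, 30)),
                        cbind(rep(0, 30), rep(1, 30)))
  set.seed(5)
  off <- generationStep(pop, arch, sourceRegime(arch), rs = 1)
  expect_true(all(off@selfed))
  g <- matrix(as.integer(off@hap1), 30) + matrix(as.integer(off@hap2), 30)
  # each offspring genome is uniformly 0s or uniformly 2s
  expect_true(all(apply(g, 2, function(x) all(x == 0) || all(x == 2))))
})

test_that("fitness-weighted sampling excludes effectively dead parents", {
  # parent 2 is homozygous deleterious everywhere with strong selection
  arch <- architectureParams(LA = 0, LR = 40, muR = 0, s = 2, h = 0.5 - 1e-9)
  pop <- makePopulation(cbind(rep(0, 40), rep(1, 40)),
                        cbind(rep(0, 40), rep(1, 40)))
  set.seed(6)
  off <- generationStep(pop, arch, sourceRegime(arch), rs = 0, nGen = 1)
  expect_true(all(off@hap1 == as.raw(0)) && all(off@hap2 == as.raw(0)))
})

test_that("population collapse (zero total fitness) raises an error", {
  arch <- architectureParams(LA = 0, LR = 10, muR = 0, s = 800, h = 0.4)
  pop <- makePopulation(matrix(1, 10, 4), matrix(1, 10, 4))
  set.seed(2)
  expect_error(generationStep(pop, arch, sourceRegime(arch), rs = 0.5),
               "collapse")
})

test_that("neutral allele frequency is a martingale across replicates", {
  arch <- architectureParams(LA = 0, LR = 25, muR = 0, s = 0, h = 0)
  reg <- sourceRegime(arch)
  set.seed(8)
  drift <- replicate(40, {
    pop <- initializePopulation(150, arch, initFreq = 0.5)
    off <- generationStep(pop, arch, reg, rs = 0, nGen = 10)
    alleleFrequency(off, arch)["R"]
  })
  se <- sd(drift) / sqrt(length(drift))
  expect_lt(abs(mean(drift) - 0.5), 4 * se + 1e-3)
})

test_that("symmetric mutation without selection equilibrates near 0.5", {
  arch <- architectureParams(LA = 0, LR = 60, muR = 0.01, s = 0, h = 0)
  reg <- sourceRegime(arch)
  set.seed(12)
  pop <- initializePopulation(300, arch)
  st <- runToStationarity(pop, arch, reg, rs = 0.3, burnIn = 600,
                          nSamples = 10, thin = 30, maxPairs = 300)
  expect_lt(abs(st@values[["pR"]] - 0.5),
            4 * st@se[["pR"]] + 0.02)
  expect_equal(st@nSamples, 10L)
})

test_that("the ID estimator reproduces a hand-computed toy population", {
  # two loci, four individuals: homozygote indicators perfectly correlated
  h <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  pop <- makePopulation(h, h)
  arch <- architectureParams(LA = 0, LR = 2, muR = 0, s = 0.01, h = 0.1)
  st <- estimateStatistics(pop, arch, sourceRegime(arch))
  # E[Xj Xk] = 0.5, p11 = 0.5, p = 0.5: ID = (0.5 - 0.25) / 0.0625 = 4
  expect_equal(unname(st@values["idRR"]), 4)
  expect_equal(unname(attr(st, "nPairs")["RR"]), 1)
  # gametic LD of identical rows is 1
  expect_equal(unname(st@values["ld"]), 1)

  # identical genomes: everything monomorphic, pairs excluded
  popM <- makePopulation(matrix(1, 2, 4), matrix(1, 2, 4))
  stM <- estimateStatistics(popM, arch, sourceRegime(arch))
  expect_true(is.na(stM@values["idRR"]))
  expect_equal(unname(attr(stM, "nPairs")["RR"]), 0)
})

test_that("delta is absent without selfed offspring and defined with them", {
  arch <- archRec(LR = 30, muR = 1e-3, s = 0.1, h = 0.1)
  reg <- sourceRegime(arch)
  set.seed(21)
  pop <- initializePopulation(200, arch, initFreq = 0.2)
  off0 <- generationStep(pop, arch, reg, rs = 0)
  st0 <- estimateStatistics(off0, arch, reg)
  expect_true(is.na(st0@values["delta"]))
  off5 <- generationStep(pop, arch, reg, rs = 0.5)
  st5 <- estimateStatistics(off5, arch, reg)
  expect_false(is.na(st5@values["delta"]))
  expect_gt(st5@values[["delta"]], 0)
})

test_that("simulation agrees with the cohort model at a reduced parameter point", {
  arch <- archBoth(LA = 50, LR = 100, muA = 1e-3, muR = 1e-3, s = 0.05,
                   h = 0.1, s0 = 0.005)
  reg <- sourceRegime(arch)
  eq <- ilecEquilibrium(arch, reg, 0.5)
  ip <- alleleFrequency(eq)
  set.seed(31)
  pop <- initializePopulation(1000, arch)
  st <- runToStationarity(pop, arch, reg, rs = 0.5, burnIn = 1200,
                          nSamples = 12, thin = 40, maxPairs = 500)
  for (q in c("A", "R")) {
    key <- paste0("p", q)
    tol <- 0.15 * ip[[q]] + 3 * st@se[[key]]
    expect_lt(abs(st@values[[key]] - ip[[q]]), tol)
  }
  smI <- populationSummaries(eq, arch, reg)
  expect_lt(abs(st@values[["meanFitness"]] - smI@values[["meanFitness"]]),
            0.1 * smI@values[["meanFitness"]] + 3 * st@se[["meanFitness"]])
  expect_lt(abs(st@values[["delta"]] - smI@values[["delta"]]),
            0.12 + 3 * st@se[["delta"]])
})
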