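test_that("trait values sum allelic contributions and span [zmin, zmax]", {
  arch <- architectureParams(LA = 2, LR = 0, muA = 0)
  # locus 1 heterozygous, locus 2 homozygous "1": z = 0 + alpha = 0.5
  pop <- makePopulation(hap1 = rbind(c(1), c(1)), hap2 = rbind(c(0), c(1)))
  expect_equal(traitValue(pop, arch), 0.5)

  allZero <- makePopulation(rbind(0, 0), rbind(0, 0))
  allOne <- makePopulation(rbind(1, 1), rbind(1, 1))
  expect_equal(traitValue(allZero, arch), unname(traitRange(arch)["zmin"]))
  expect_equal(traitValue(allOne, arch), unname(traitRange(arch)["zmax"]))
  expect_equal(traitRange(arch), c(zmin = -1, zmax = 1))
})

test_that("trait ignores recessive loci and checks genome length", {
  arch <- archBoth(LA = 2, LR = 3)
  h1 <- matrix(c(1, 0, 1, 1, 1), ncol = 1)
  h2 <- matrix(c(0, 0, 1, 0, 1), ncol = 1)
  pop <- makePopulation(h1, h2)
  # only the 2 additive rows contribute: 1 allele "1" -> zmin + alpha
  expect_equal(traitValue(pop, arch), -1 + 0.5)
  badArch <- archBoth(LA = 2, LR = 4)
  expect_error(traitValue(pop, badArch), "genome length")
})

test_that("fitness matches the exponential load form in both habitats", {
  arch <- architectureParams(LA = 0, LR = 3, muR = 0, s = 0.05, h = 0.1)
  reg <- sourceRegime(arch)
  # exactly one recessive homozygote, z at zmin
  pop <- makePopulation(matrix(c(1, 0, 0), ncol = 1),
                        matrix(c(1, 0, 0), ncol = 1))
  expect_equal(individualFitness(pop, arch, reg), exp(-0.05))

  # all-"0" genome is fittest in source, and mirrored on the island
  arch2 <- architectureParams(LA = 4, LR = 2, muA = 0, muR = 0, s = 0.05,
                              h = 0.1, s0Tilde = 0.01)
  z0 <- makePopulation(matrix(0, 6, 1), matrix(0, 6, 1))
  expect_equal(individualFitness(z0, arch2, sourceRegime(arch2)), 1)
  isl <- islandRegime(arch2, s1Tilde = 0.02)
  expect_equal(individualFitness(z0, arch2, isl),
               exp(-2 * 0.02 * arch2@LA))
})

test_that("load decomposes additively and equals -log fitness", {
  arch <- archBoth(LA = 5, LR = 5, s = 0.05, h = 0.1, s0 = 0.003)
  reg <- sourceRegime(arch)
  set.seed(42)
  pop <- initializePopulation(30, arch, initFreq = 0.4)
  G <- geneticLoad(pop, arch, reg)
  expect_equal(G, geneticLoad(pop, arch, reg, "additive") +
                 geneticLoad(pop, arch, reg, "recessive"))
  expect_equal(G, -log(individualFitness(pop, arch, reg)))
  # one recessive heterozygote: G = h*s
  one <- makePopulation(matrix(c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0), ncol = 1),
                        matrix(0, 10, 1))
  expect_equal(geneticLoad(one, arch, reg, "recessive"), 0.1 * 0.05)
})

test_that("per-locus genotype weights are the stated geometric ladders", {
  arch <- archBoth(LA = 1, LR = 1, s = 0.04, h = 0.2, s0 = 0.006)
  mk <- function(a1, a2, r1, r2)
    makePopulation(matrix(c(a1, r1), ncol = 1), matrix(c(a2, r2), ncol = 1))
  wsrc <- function(p) individualFitness(p, arch, sourceRegime(arch))
  # additive genotypes 00, 01, 11 in the source
  w <- c(wsrc(mk(0, 0, 0, 0)), wsrc(mk(1, 0, 0, 0)), wsrc(mk(1, 1, 0, 0)))
  expect_equal(w / w[1], c(1, exp(-0.006), exp(-2 * 0.006)))
  # island mirrors the ladder with s1~ and reversed genotype order
  isl <- islandRegime(arch, s1Tilde = 0.01)
  wi <- c(individualFitness(mk(0, 0, 0, 0), arch, isl),
          individualFitness(mk(1, 0, 0, 0), arch, isl),
          individualFitness(mk(1, 1, 0, 0), arch, isl))
  expect_equal(wi / wi[3], c(exp(-2 * 0.01), exp(-0.01), 1))
  # recessive ladder 1, e^{-hs}, e^{-s}
  wr <- c(wsrc(mk(0, 0, 0, 0)), wsrc(mk(0, 0, 1, 0)), wsrc(mk(0, 0, 1, 1)))
  expect_equal(wr / wr[1], c(1, exp(-0.2 * 0.04), exp(-0.04)))
})

test_that("fitness is monotone in homozygote, heterozygote and trait counts", {
  arch <- archBoth(LA = 6, LR = 6, s = 0.05, h = 0.1, s0 = 0.004)
  reg <- sourceRegime(arch)
  L <- 12
  base <- matrix(0, L, 1)
  wOf <- function(h1, h2) individualFitness(makePopulation(h1, h2), arch, reg)
  w0 <- wOf(base, base)
  for (k in 1:6) {
    hom <- base; hom[6 + seq_len(k), 1] <- 1
    expect_lt(wOf(hom, hom), if (k == 1) w0 else wPrev)
    wPrev <- wOf(hom, hom)
  }
  # adding "1" additive alleles moves z away from the source optimum
  wAdd <- vapply(0:6, function(k) {
    h1 <- base; if (k > 0) h1[seq_len(k), 1] <- 1
    wOf(h1, base)
  }, numeric(1))
  expect_true(all(diff(wAdd) < 0))
})

test_that("architecture invariants are enforced", {
  expect_error(architectureParams(LA = 10, LR = 10, muA = 0.7),
               "rate in \\[0, 0.5\\]")
  expect_error(architectureParams(LA = 10, LR = 0, h = 0.5), "h must")
  expect_error(architectureParams(LA = 0, LR = 0), "at least one locus")
  arch <- architectureParams(LA = 250, LR = 100, muA = 1e-4, muR = 2e-4,
                             s0Tilde = 0.004)
  expect_equal(alphaEffect(arch) * arch@LA, 1)
  expect_equal(genomicMutationRate(arch),
               c(A = 2 * 1e-4 * 250, R = 2 * 2e-4 * 100))
  expect_equal(s0Tilde(arch), 0.004)
})
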