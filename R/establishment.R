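#' @include population.R
NULL

#' Sample founder genomes from a cohort-model equilibrium
#'
#' Each founder is assigned a selfing age i with probability f_i, then every
#' locus independently receives genotype 00, 01/10 or 11 with that cohort's
#' equilibrium frequencies (heterozygote phase randomized). Independence
#' across loci reflects the within-cohort equilibrium assumption; there is
#' no identity by descent due to drift among founders.
#'
#' @param state a converged [CohortState-class] (refused otherwise).
#' @param arch an [ArchitectureParams-class].
#' @param N0 number of founders.
#' @return A [DiploidPopulation-class] with selfing ages set.
#' @export
sampleFounders <- function(state, arch, N0) {
  if (!isConverged(state))
    stop("refusing to sample founders from a non-converged cohort state")
  stopifnot(N0 >= 1)
  n <- length(state@f)
  ages <- sample.int(n, N0, replace = TRUE, prob = state@f) - 1L
  L <- arch@LA + arch@LR
  h1 <- matrix(0L, L, N0); h2 <- matrix(0L, L, N0)
  fillBlock <- function(rows, p01, p11) {
    if (!length(rows)) return()
    Lb <- length(rows)
    u <- matrix(stats::runif(Lb * N0), Lb, N0)
    t11 <- matrix(p11[ages + 1L], Lb, N0, byrow = TRUE)
    t01 <- matrix(p01[ages + 1L], Lb, N0, byrow = TRUE)
    hom <- u < t11
    het <- !hom & u < t11 + t01
    phase <- matrix(stats::runif(Lb * N0) < 0.5, Lb, N0)
    h1[rows, ][hom | (het & phase)] <<- 1L
    h2[rows, ][hom | (het & !phase)] <<- 1L
  }
  fillBlock(seq_len(arch@LA), state@p01A, state@p11A)
  fillBlock(arch@LA + seq_len(arch@LR), state@p01R, state@p11R)
  new("DiploidPopulation",
      hap1 = matrix(as.raw(h1), nrow = L),
      hap2 = matrix(as.raw(h2), nrow = L),
      selfingAge = as.integer(ages), selfed = ages > 0L, generation = 0L)
}

#' Hard-selection demographic update
#'
#' Offspring number is Poisson with mean N_t * exp(r0 (1 - N_t/K)) * Wbar_t
#' (Ricker density regulation scaled by mean fitness; K = Inf gives pure
#' exponential growth e^{r0} Wbar). N = 0 is absorbing.
#'
#' @param Nt current population size.
#' @param wbar current mean fitness in [0, 1].
#' @param island an [IslandParams-class] (uses r0 and K).
#' @return Integer N_{t+1} drawn from the current RNG stream.
#' @export
demographicUpdate <- function(Nt, wbar, island) {
  stopifnot(Nt >= 0, wbar >= 0, wbar <= 1)
  if (Nt == 0) return(0L)
  dens <- if (is.finite(island@K)) exp(island@r0 * (1 - Nt / island@K))
          else exp(island@r0)
  as.integer(stats::rpois(1, Nt * dens * wbar))
}

establishCall <- function(founders, arch, island, regimeHabitat = "island",
                          successN = NULL, stopAtThreshold = FALSE,
                          sfsGen = -1L, keepFinal = FALSE) {
  s1 <- if (regimeHabitat == "island")
    sTildeOf(islandRegime(arch, beta1 = island@beta1), arch)
  else s0Tilde(arch)
  if (is.null(successN)) successN <- island@successFraction * island@K
  cpp_establish(founders@hap1, founders@hap2, arch@LA, arch@LR, arch@muA,
                arch@muR, arch@s, arch@h, s1,
                regimeHabitat == "island", island@rs, island@r0,
                if (is.finite(island@K)) island@K else -1,
                island@Tgen, successN, stopAtThreshold,
                as.integer(sfsGen), keepFinal)
}

#' Simulate one colonization attempt
#'
#' Generations on the island: mutation, island-regime fitness, Poisson hard
#' selection via [demographicUpdate()], then each offspring selfs with
#' probability rs or outcrosses with independently drawn (possibly
#' identical) fitness-weighted parents -- so the realized selfing fraction
#' exceeds rs at small N and equals 1 for a lone individual. Success means
#' N at generation Tgen is at least successFraction * K; extinction
#' short-circuits.
#'
#' @param founders a [DiploidPopulation-class] of founders.
#' @param arch an [ArchitectureParams-class].
#' @param island an [IslandParams-class].
#' @param sfsGen generation at which to snapshot additive allele
#'   frequencies (-1 for none).
#' @param keepFinal return the surviving population's haplotypes.
#' @return list(success, N, wbar, extinctGen, tEnd, sfs, ...).
#' @export
establishmentReplicate <- function(founders, arch, island, sfsGen = -1,
                                   keepFinal = FALSE) {
  checkGenomeLength(founders, arch)
  establishCall(founders, arch, island, "island", sfsGen = sfsGen,
                keepFinal = keepFinal)
}

#' Estimate the establishment probability
#'
#' Runs `R` independent colonization events, each with fresh founders drawn
#' from the source equilibrium, and returns the success fraction with its
#' binomial standard error. Replicates are made independent by sub-seeds
#' derived from `seed` with a fixed splitting rule ([subSeed()]); with
#' `seed = NULL` the current RNG stream is used sequentially.
#'
#' @param state converged source [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param island an [IslandParams-class].
#' @param R number of replicates.
#' @param sfsGen snapshot generation for the adaptive-allele SFS (-1: none).
#' @param seed optional master seed.
#' @return An [EstablishmentResult-class].
#' @export
estimateEstablishmentProbability <- function(state, arch, island, R,
                                             sfsGen = -1, seed = NULL) {
  stopifnot(R >= 1)
  success <- logical(R)
  traj <- vector("list", R)
  wtraj <- vector("list", R)
  sfsList <- if (sfsGen >= 0) vector("list", R) else NULL
  for (r in seq_len(R)) {
    if (!is.null(seed)) set.seed(subSeed(seed, r))
    founders <- sampleFounders(state, arch, island@N0)
    res <- establishmentReplicate(founders, arch, island, sfsGen = sfsGen)
    success[r] <- res$success
    traj[[r]] <- res$N
    wtraj[[r]] <- res$wbar
    if (sfsGen >= 0 && length(res$sfs)) sfsList[[r]] <- res$sfs
  }
  p <- mean(success)
  sfs <- NULL
  if (!is.null(sfsList)) {
    keep <- !vapply(sfsList, is.null, logical(1))
    if (any(keep)) sfs <- do.call(rbind, sfsList[keep])
  }
  new("EstablishmentResult", success = success, pEst = p,
      se = sqrt(p * (1 - p) / R), trajectories = traj,
      wbarTrajectories = wtraj, sfs = sfs,
      params = list(island = island, R = R, sfsGen = sfsGen),
      seed = if (is.null(seed)) NA else seed)
}

#' @describeIn pEstimate point estimate and binomial SE.
#' @export
setMethod("pEstimate", "EstablishmentResult", function(x)
  c(pEst = x@pEst, se = x@se))

#' Branching-process approximation to the establishment probability
#'
#' Each founder line is an independent Poisson branching process with mean
#' offspring number m_k = e^{r0} W_k; the per-line extinction probability
#' solves q = exp[m (q - 1)] (smallest root, found by fixed-point iteration
#' from 0), and P_est = 1 - prod_k q_k. With a single pooled mean fitness
#' and N0 lines, P_est = 1 - q^{N0}. Subcritical lines (m <= 1) go extinct
#' with certainty.
#'
#' @param founderFitness vector of founder fitnesses in [0, 1] (one entry
#'   per founder), or a single pooled mean fitness.
#' @param r0 intrinsic growth rate.
#' @param N0 number of founders when a pooled fitness is given (default:
#'   length of `founderFitness`).
#' @return Approximate establishment probability.
#' @export
branchingProcessPest <- function(founderFitness, r0, N0 = NULL) {
  stopifnot(all(founderFitness >= 0), all(founderFitness <= 1))
  if (is.null(N0)) N0 <- 1  # exponent per entry
  m <- exp(r0) * founderFitness
  q <- vapply(m, function(mk) {
    if (mk <= 1) return(1)
    qk <- 0
    for (it in seq_len(100000L)) {
      qn <- exp(mk * (qk - 1))
      if (abs(qn - qk) < 1e-12) return(qn)
      qk <- qn
    }
    stop("extinction-probability fixed point did not converge")
  }, numeric(1))
  1 - prod(q^N0)
}

#' Source-population viability pre-check under hard selection
#'
#' Tests that founders from the source equilibrium are demographically
#' viable under source-habitat selection: N0 = 100 individuals must double
#' (reach 200) within 100 generations with probability greater than 0.95,
#' with effectively infinite K. Used to restrict establishment scans to
#' parameters for which a large source population could persist at all.
#'
#' @param state converged source [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param rs selfing fraction.
#' @param r0 intrinsic growth rate.
#' @param replicates number of replicate populations.
#' @param N0 starting size.
#' @param Tgen horizon.
#' @return list(viable, fraction, se).
#' @export
viabilityCheck <- function(state, arch, rs, r0 = 1.1, replicates = 100,
                           N0 = 100, Tgen = 100) {
  isl <- new("IslandParams", beta1 = 0, r0 = r0, K = Inf,
             N0 = as.integer(N0), Tgen = as.integer(Tgen),
             successFraction = 1, rs = rs)
  ok <- logical(replicates)
  for (r in seq_len(replicates)) {
    founders <- sampleFounders(state, arch, N0)
    res <- establishCall(founders, arch, isl, "source", successN = 2 * N0,
                         stopAtThreshold = TRUE)
    ok[r] <- res$success
  }
  fr <- mean(ok)
  list(viable = fr > 0.95, fraction = fr,
       se = sqrt(fr * (1 - fr) / replicates))
}

#' Site frequency spectrum of island-adaptive additive alleles
#'
#' Per additive locus, the frequency of the island-favored "1" allele,
#' binned over [0, 1] with the fixed classes 0 and 1 kept separate. Counts
#' sum to LA.
#'
#' @param x a [DiploidPopulation-class], or a numeric vector of per-locus
#'   frequencies (e.g. an establishment snapshot).
#' @param arch an [ArchitectureParams-class] (used for a population).
#' @param bins number of interior bins spanning (0, 1).
#' @return data.frame(lower, upper, count) whose first and last rows are
#'   the fixed classes [0,0] and [1,1].
#' @export
adaptiveAlleleSFS <- function(x, arch = NULL, bins = 10) {
  if (is(x, "DiploidPopulation")) {
    stopifnot(!is.null(arch))
    checkGenomeLength(x, arch)
    if (arch@LA == 0L) stop("no additive loci in this architecture")
    hp <- intHaps(x)
    rows <- seq_len(arch@LA)
    freqs <- rowMeans(hp$h1[rows, , drop = FALSE] +
                        hp$h2[rows, , drop = FALSE]) / 2
  } else freqs <- as.numeric(x)
  stopifnot(all(freqs >= 0), all(freqs <= 1))
  br <- seq(0, 1, length.out = bins + 1L)
  interior <- freqs > 0 & freqs < 1
  cut0 <- sum(freqs == 0)
  cut1 <- sum(freqs == 1)
  cts <- if (any(interior))
    hist(freqs[interior], breaks = br, plot = FALSE)$counts
  else integer(bins)
  data.frame(lower = c(0, br[-length(br)], 1),
             upper = c(0, br[-1], 1),
             count = c(cut0, cts, cut1))
}
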