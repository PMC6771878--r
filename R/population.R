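#' @include ilec-summaries.R
NULL

#' Initialize an explicit diploid population
#'
#' Each allele is drawn independently with the given "1"-allele frequency
#' (one value, or one per locus type). The default starts monomorphic for
#' the favorable allele; equilibrium statistics are initialization-
#' independent after burn-in.
#'
#' @param N number of individuals.
#' @param arch an [ArchitectureParams-class].
#' @param initFreq initial "1"-allele frequency; scalar or c(A=, R=).
#' @return A [DiploidPopulation-class]. Uses the current RNG stream;
#'   set.seed() for reproducibility.
#' @export
initializePopulation <- function(N, arch, initFreq = 0) {
  stopifnot(N >= 1)
  L <- arch@LA + arch@LR
  if (length(initFreq) == 1L) initFreq <- c(A = initFreq, R = initFreq)
  pRow <- c(rep(initFreq[["A"]], arch@LA), rep(initFreq[["R"]], arch@LR))
  draw <- function() matrix(as.raw(stats::rbinom(L * N, 1L, rep(pRow, N))),
                            nrow = L)
  new("DiploidPopulation", hap1 = draw(), hap2 = draw(),
      selfingAge = integer(N), selfed = logical(N), generation = 0L)
}

#' Advance a population by whole generations
#'
#' One generation is: symmetric mutation at every allele, fitness
#' evaluation, fitness-weighted parent sampling with replacement, a selfing
#' decision per offspring (probability rs; outcross partners drawn
#' independently and may coincide with the first parent), and gamete
#' formation by free recombination. Population size stays constant.
#'
#' @param pop a [DiploidPopulation-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param rs selfing fraction in [0, 1].
#' @param nGen number of generations to advance.
#' @return The offspring [DiploidPopulation-class] with updated selfing-age
#'   and realized-selfing metadata.
#' @export
generationStep <- function(pop, arch, regime, rs, nGen = 1) {
  checkGenomeLength(pop, arch)
  stopifnot(rs >= 0, rs <= 1, nGen >= 1)
  res <- cpp_evolve_source(pop@hap1, pop@hap2, pop@selfingAge, arch@LA,
                           arch@LR, arch@muA, arch@muR, arch@s, arch@h,
                           sTildeOf(regime, arch),
                           regime@habitat == "island", rs, as.integer(nGen))
  if (isTRUE(res$collapsed))
    stop("population collapse: total fitness is zero, nobody can breed")
  new("DiploidPopulation", hap1 = res$hap1, hap2 = res$hap2,
      selfingAge = res$age, selfed = as.logical(res$selfed),
      generation = pop@generation + as.integer(nGen))
}

# AR(1)-corrected standard error of the mean of (possibly autocorrelated)
# stationary samples
seriesSE <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  v <- stats::var(x)
  if (v == 0) return(0)
  rho <- if (n >= 3L) stats::cor(x[-1], x[-n]) else 0
  if (is.na(rho)) rho <- 0
  rho <- min(max(rho, 0), 0.95)
  sqrt(v / n * (1 + rho) / (1 - rho))
}

#' Census statistics of an explicit population
#'
#' Allele frequencies by counting; pairwise identity disequilibrium for a
#' seeded random subsample of locus pairs, using the estimator
#' \[mean(Xj Xk) - mean(Xj) mean(Xk)\] / \[pj(1-pj) pk(1-pk)\] with X the
#' "11"-homozygote indicator and p the allele frequency; gametic LD as the
#' correlation r over the 2N haplotypes for the same pairs; mean fitness;
#' inbreeding depression from the realized selfing labels of the current
#' offspring generation; heterozygosity; and a load histogram. Monomorphic
#' loci are excluded from ID/LD pairs (count reported via attribute
#' `nPairs`).
#'
#' @param pop a [DiploidPopulation-class] at census.
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param maxPairs cap on sampled locus pairs per type pair.
#' @return A [SummaryStats-class] with source `"simulation"`.
#' @export
estimateStatistics <- function(pop, arch, regime, maxPairs = 2000) {
  checkGenomeLength(pop, arch)
  hp <- intHaps(pop)
  N <- ncol(hp$h1)
  LA <- arch@LA; LR <- arch@LR
  g <- hp$h1 + hp$h2
  L <- nrow(g)
  pLoc <- .rowMeans(g, L, N) / 2            # per-locus allele frequency
  X <- matrix(as.double(g == 2L), L, N)     # "11"-homozygote indicator
  p11Loc <- .rowMeans(X, L, N)
  poly <- pLoc > 0 & pLoc < 1

  idxA <- seq_len(LA)
  idxR <- LA + seq_len(LR)
  pA <- if (LA > 0L) mean(pLoc[idxA]) else NA_real_
  pR <- if (LR > 0L) mean(pLoc[idxR]) else NA_real_

  H <- matrix(as.double(cbind(hp$h1, hp$h2)), L, 2L * N)  # 2N haplotypes
  pHapLoc <- .rowMeans(H, L, 2L * N)
  pairStats <- function(js, ks) {
    keep <- poly[js] & poly[ks]
    js <- js[keep]; ks <- ks[keep]
    if (!length(js)) return(c(id = NA_real_, ld = NA_real_, n = 0))
    m <- length(js)
    exx <- .rowMeans(X[js, , drop = FALSE] * X[ks, , drop = FALSE], m, N)
    idv <- (exx - p11Loc[js] * p11Loc[ks]) /
      (pLoc[js] * (1 - pLoc[js]) * pLoc[ks] * (1 - pLoc[ks]))
    ehh <- .rowMeans(H[js, , drop = FALSE] * H[ks, , drop = FALSE], m, 2L * N)
    pj <- pHapLoc[js]; pk <- pHapLoc[ks]
    ldv <- (ehh - pj * pk) / sqrt(pj * (1 - pj) * pk * (1 - pk))
    c(id = mean(idv), ld = mean(ldv), n = m)
  }
  samplePairs <- function(idx1, idx2, same) {
    n1 <- length(idx1); n2 <- length(idx2)
    total <- if (same) n1 * (n1 - 1) / 2 else as.numeric(n1) * n2
    if (total < 1) return(NULL)
    if (total <= maxPairs) {      # enumerate every pair when feasible
      if (same) {
        cb <- utils::combn(idx1, 2)
        return(list(j = cb[1, ], k = cb[2, ]))
      }
      gr <- expand.grid(j = idx1, k = idx2)
      return(list(j = gr$j, k = gr$k))
    }
    if (same) {
      js <- sample(idx1, maxPairs, replace = TRUE)
      ks <- sample(idx1, maxPairs, replace = TRUE)
      ok <- js != ks
      list(j = js[ok], k = ks[ok])
    } else {
      list(j = sample(idx1, maxPairs, replace = TRUE),
           k = sample(idx2, maxPairs, replace = TRUE))
    }
  }
  idFor <- function(pp) {
    if (is.null(pp)) return(c(id = NA_real_, ld = NA_real_, n = 0))
    pairStats(pp$j, pp$k)
  }
  sAA <- idFor(if (LA > 1L) samplePairs(idxA, idxA, TRUE))
  sRR <- idFor(if (LR > 1L) samplePairs(idxR, idxR, TRUE))
  sAR <- idFor(if (LA > 0L && LR > 0L) samplePairs(idxA, idxR, FALSE))

  w <- individualFitness(pop, arch, regime)
  W <- mean(w)
  selfed <- pop@selfed
  delta <- if (any(selfed) && any(!selfed))
    1 - mean(w[selfed]) / mean(w[!selfed]) else NA_real_

  hetLoc <- rowMeans(g == 1L)
  hetA <- if (LA > 0L) mean(hetLoc[idxA]) else NA_real_
  hetR <- if (LR > 0L) mean(hetLoc[idxR]) else NA_real_

  G <- -log(w)
  rg <- range(G)
  if (diff(rg) == 0) rg <- rg + c(-1e-6, 1e-6)
  br <- seq(rg[1] - 1e-12, rg[2] + 1e-12, length.out = 41)
  lh <- hist(G, breaks = br, plot = FALSE)
  loadHist <- data.frame(G = lh$mids, prob = lh$counts / length(G))

  vals <- c(pA = pA, pR = pR, meanFitness = W,
            wbarOut = if (any(!selfed)) mean(w[!selfed]) else NA_real_,
            wbarSelf = if (any(selfed)) mean(w[selfed]) else NA_real_,
            delta = delta, idAA = unname(sAA["id"]),
            idRR = unname(sRR["id"]), idAR = unname(sAR["id"]),
            ld = unname(mean(c(sAA["ld"], sRR["ld"], sAR["ld"]),
                             na.rm = TRUE)),
            hetA = hetA, hetR = hetR)
  out <- new("SummaryStats", values = vals, se = numeric(0), nSamples = 1L,
             source = "simulation", samples = NULL, loadHist = loadHist)
  attr(out, "nPairs") <- c(AA = unname(sAA["n"]), RR = unname(sRR["n"]),
                           AR = unname(sAR["n"]))
  out
}

#' Evolve to stationarity and average statistics
#'
#' Evolves `burnIn` generations, then records census statistics every
#' `thin` generations, `nSamples` times, and returns their averages with
#' autocorrelation-corrected between-sample standard errors.
#'
#' @param pop starting [DiploidPopulation-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param rs selfing fraction.
#' @param burnIn burn-in generations before sampling.
#' @param nSamples number of recorded samples.
#' @param thin generations between samples.
#' @param maxPairs cap on locus pairs for the ID/LD estimators.
#' @return A [SummaryStats-class] with source `"simulation"`; slot
#'   `samples` holds the per-sample records.
#' @export
runToStationarity <- function(pop, arch, regime, rs, burnIn = 5000,
                              nSamples = 20, thin = 100, maxPairs = 2000) {
  stopifnot(burnIn >= 1, thin >= 1, nSamples >= 1)
  pop <- generationStep(pop, arch, regime, rs, nGen = burnIn)
  recs <- vector("list", nSamples)
  for (k in seq_len(nSamples)) {
    st <- estimateStatistics(pop, arch, regime, maxPairs = maxPairs)
    recs[[k]] <- st@values
    if (k < nSamples) pop <- generationStep(pop, arch, regime, rs,
                                            nGen = thin)
  }
  tab <- do.call(rbind, recs)
  vals <- colMeans(tab, na.rm = TRUE)
  vals[colSums(!is.na(tab)) == 0L] <- NA_real_
  ses <- apply(tab, 2, seriesSE)
  out <- new("SummaryStats", values = vals, se = ses,
             nSamples = as.integer(nSamples), source = "simulation",
             samples = as.data.frame(tab), loadHist = NULL)
  # stationarity diagnostic: first- vs second-half sample means, in units
  # of the (autocorrelation-corrected) SE; large values indicate drifting
  # statistics and too short a burn-in
  if (nSamples >= 4L) {
    half <- seq_len(nSamples %/% 2L)
    d <- colMeans(tab[half, , drop = FALSE], na.rm = TRUE) -
      colMeans(tab[-half, , drop = FALSE], na.rm = TRUE)
    attr(out, "stationarity") <- d / (sqrt(2) * ses)
  }
  out
}
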