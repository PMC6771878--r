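#' @include ilec-equilibrium.R
NULL

# product-form expected fitness of each cohort at census
cohortLogMeanFitness <- function(state, arch, regime) {
  w <- genotypeWeights(arch, regime)
  nuA <- (1 - state@p01A - state@p11A) * w$A[1] + state@p01A * w$A[2] +
    state@p11A * w$A[3]
  nuR <- (1 - state@p01R - state@p11R) * w$R[1] + state@p01R * w$R[2] +
    state@p11R * w$R[3]
  arch@LA * log(nuA) + arch@LR * log(nuR)
}

#' Pairwise identity disequilibrium predicted by the cohort model
#'
#' Between-cohort variance (or, for mixed type pairs, covariance) of the
#' homozygote frequency, normalized by the product of per-type allelic
#' variances: for two loci of the same type,
#' ID = sum_{j<i} f_i f_j (p11(i) - p11(j))^2 / (p^2 (1-p)^2). For an
#' additive-recessive pair the numerator is the between-cohort covariance of
#' p11A and p11R and the normalizer is pA(1-pA) * pR(1-pR) -- the natural
#' generalization to nonidentical loci (the same-type formula is the special
#' case of identical loci).
#'
#' @param state a census [CohortState-class].
#' @param typePair one of "AA", "RR", "AR".
#' @return Normalized ID (nonnegative for same-type pairs); NA if either
#'   locus type involved is monomorphic.
#' @export
pairwiseIdentityDisequilibrium <- function(state,
                                           typePair = c("AA", "RR", "AR")) {
  typePair <- match.arg(typePair)
  f <- state@f
  p <- alleleFrequency(state)
  mixCov <- function(a, b) sum(f * a * b) - sum(f * a) * sum(f * b)
  num <- switch(typePair,
                AA = mixCov(state@p11A, state@p11A),
                RR = mixCov(state@p11R, state@p11R),
                AR = mixCov(state@p11A, state@p11R))
  usesA <- typePair %in% c("AA", "AR")
  usesR <- typePair %in% c("RR", "AR")
  eps <- 1e-12
  mono <- function(q) q <= eps || q >= 1 - eps
  if ((usesA && mono(p["A"])) || (usesR && mono(p["R"])))
    return(NA_real_)
  den <- switch(typePair,
                AA = (p[["A"]] * (1 - p[["A"]]))^2,
                RR = (p[["R"]] * (1 - p[["R"]]))^2,
                AR = p[["A"]] * (1 - p[["A"]]) * p[["R"]] * (1 - p[["R"]]))
  num / den
}

#' Population summaries from a cohort state
#'
#' Census-level quantities implied by the cohort approximation: allele
#' frequencies, mean fitness Wbar = sum_i f_i wbar_i (with wbar_i the
#' product-form cohort fitness), inbreeding depression
#' delta = 1 - Wbar_self / Wbar_oc (outcrossed = cohort 0, selfed = all
#' cohorts with age >= 1, weighted by census masses), mean heterozygosity
#' per type, and the three pairwise identity disequilibria.
#'
#' @param state a census [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @return A [SummaryStats-class] with source `"ilec"`.
#' @export
populationSummaries <- function(state, arch, regime) {
  f <- state@f
  logw <- cohortLogMeanFitness(state, arch, regime)
  wbar <- exp(logw)
  W <- sum(f * wbar)
  wOut <- wbar[1]
  fSelf <- sum(f[-1])
  wSelf <- if (fSelf > 0) sum(f[-1] * wbar[-1]) / fSelf else NA_real_
  delta <- if (fSelf > 0) 1 - wSelf / wOut else NA_real_
  p <- alleleFrequency(state)
  if (arch@LA == 0L) p["A"] <- NA_real_
  if (arch@LR == 0L) p["R"] <- NA_real_
  vals <- c(pA = unname(p["A"]), pR = unname(p["R"]), meanFitness = W,
            wbarOut = wOut, wbarSelf = wSelf, delta = delta,
            idAA = if (arch@LA > 0L)
              pairwiseIdentityDisequilibrium(state, "AA") else NA_real_,
            idRR = if (arch@LR > 0L)
              pairwiseIdentityDisequilibrium(state, "RR") else NA_real_,
            idAR = if (arch@LA > 0L && arch@LR > 0L)
              pairwiseIdentityDisequilibrium(state, "AR") else NA_real_,
            ld = NA_real_,
            hetA = if (arch@LA > 0L) sum(f * state@p01A) else NA_real_,
            hetR = if (arch@LR > 0L) sum(f * state@p01R) else NA_real_)
  new("SummaryStats", values = vals, se = numeric(0), nSamples = 0L,
      source = "ilec", samples = NULL, loadHist = NULL)
}

#' @describeIn meanFitness extract mean fitness from summary statistics.
#' @export
setMethod("meanFitness", "SummaryStats", function(x, ...)
  unname(x@values["meanFitness"]))

#' @describeIn inbreedingDepression extract delta from summary statistics.
#' @export
setMethod("inbreedingDepression", "SummaryStats", function(x, ...)
  unname(x@values["delta"]))

#' @describeIn meanFitness ILEC mean fitness of a cohort state.
#' @export
setMethod("meanFitness", "CohortState", function(x, arch, regime, ...)
  sum(x@f * exp(cohortLogMeanFitness(x, arch, regime))))

#' @describeIn inbreedingDepression ILEC inbreeding depression of a cohort
#'   state (NA when no selfed class exists, e.g. rs = 0).
#' @export
setMethod("inbreedingDepression", "CohortState",
  function(x, arch, regime, ...)
    unname(populationSummaries(x, arch, regime)@values["delta"]))

#' Neutral identity disequilibrium under partial selfing
#'
#' Equilibrium ID between two unlinked neutral loci in an infinite partially
#' selfing population, from the exact selfing-age decomposition: cohort
#' masses f_i = (1 - rs) rs^i, outcrossed offspring at Hardy-Weinberg
#' proportions, heterozygosity halving with each generation of selfing.
#' With p11(i) = q - H0 2^{-(i+1)} (H0 = 2q(1-q)) the normalized ID reduces
#' to sum_{j<i} f_i f_j (2^{-i} - 2^{-j})^2, independent of the allele
#' frequency q. Vanishes at rs = 0 and in the rs -> 1 limit, and is maximal
#' at intermediate selfing.
#'
#' @param rs selfing fraction in [0, 1].
#' @param maxAge truncation age for the geometric sum (error O(rs^maxAge)).
#' @return Neutral pairwise ID (a pure number).
#' @export
neutralIDReference <- function(rs, maxAge = 300) {
  stopifnot(all(rs >= 0), all(rs <= 1))
  vapply(rs, function(r) {
    if (r <= 0 || r >= 1) return(0)
    i <- 0:maxAge
    f <- (1 - r) * r^i
    x <- 2^(-i)
    m1 <- sum(f * x); m2 <- sum(f * x^2)
    (m2 - m1^2)  # = sum_{j<i} f_i f_j (x_i - x_j)^2
  }, numeric(1))
}

## ---- load distribution ----------------------------------------------------

numericGcd <- function(vals, rel = 1e-8) {
  vals <- vals[vals > 0]
  if (!length(vals)) return(0)
  tol <- max(vals) * rel
  g2 <- function(x, y) {
    while (y > tol) {
      r <- x - floor(x / y + 1e-12) * y
      if (r < tol || y - r < tol) r <- 0
      x <- y; y <- r
    }
    x
  }
  Reduce(g2, vals)
}

# sparse pmf on an integer grid: list(off = first index, p = probabilities)
pmfTrim <- function(pm, eps = 1e-15) {
  cs <- cumsum(pm$p)
  lo <- which(cs > eps)[1]
  hi <- which(cs >= cs[length(cs)] - eps)[1]
  p <- pm$p[lo:hi]
  list(off = pm$off + lo - 1L, p = p / sum(p))
}

pmfConv <- function(a, b) {
  na <- length(a$p); nb <- length(b$p)
  n <- stats::nextn(na + nb - 1L, 2)
  fa <- stats::fft(c(a$p, numeric(n - na)))
  fb <- stats::fft(c(b$p, numeric(n - nb)))
  p <- Re(stats::fft(fa * fb, inverse = TRUE)) / n
  p <- p[seq_len(na + nb - 1L)]
  p[p < 0] <- 0
  pmfTrim(list(off = a$off + b$off, p = p))
}

pmfPower <- function(pm, L) {
  out <- NULL
  sq <- pmfTrim(pm)
  while (L > 0) {
    if (L %% 2 == 1) out <- if (is.null(out)) sq else pmfConv(out, sq)
    L <- L %/% 2
    if (L > 0) sq <- pmfConv(sq, sq)
  }
  if (is.null(out)) list(off = 0L, p = 1) else out
}

# pmf of total load of one cohort on grid step d
cohortLoadPmf <- function(p01A, p11A, p01R, p11R, arch, st, d) {
  pm <- list(off = 0L, p = 1)
  if (arch@LR > 0L) {
    kh <- as.integer(round(arch@h * arch@s / d))
    ks <- as.integer(round(arch@s / d))
    p <- numeric(ks + 1L)
    p[1] <- 1 - p01R - p11R
    p[kh + 1L] <- p[kh + 1L] + p01R
    p[ks + 1L] <- p[ks + 1L] + p11R
    pm <- pmfConv(pm, pmfPower(list(off = 0L, p = p), arch@LR))
  }
  if (arch@LA > 0L && st > 0) {
    k1 <- as.integer(round(st / d))
    p <- numeric(2L * k1 + 1L)
    p[1] <- 1 - p01A - p11A
    p[k1 + 1L] <- p[k1 + 1L] + p01A
    p[2L * k1 + 1L] <- p[2L * k1 + 1L] + p11A
    pm <- pmfConv(pm, pmfPower(list(off = 0L, p = p), arch@LA))
  }
  pm
}

#' Distribution of genetic load implied by a cohort state
#'
#' Within a cohort, per-locus genotypes are independent and trinomially
#' distributed, so the counts of heterozygous and homozygous loci per type
#' are multinomial and the load G = s(n11R + h n01R) + s~ (2 n11A + n01A)
#' (with s~ the per-allele trait selection strength of the regime; on the
#' island the additive term counts "0" alleles) has an exactly computable
#' distribution: the locus-type components are convolved on a common grid
#' and the cohorts mixed with weights f_i. When the load increments (hs, s,
#' s~) are not commensurate the distribution is estimated by Monte-Carlo
#' multinomial sampling instead.
#'
#' @param state a census [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param resolution optional bin width for the returned histogram; default
#'   keeps the exact grid (exact method) or uses range/200 (Monte Carlo).
#' @param method "auto" picks exact convolution when increments are
#'   commensurate, otherwise Monte Carlo.
#' @param nDraws Monte-Carlo sample size.
#' @return data.frame with columns `G`, `prob` (mixture probability),
#'   `probOutcrossed` and `probSelfed` (conditional distributions of the
#'   age-0 cohort and of all selfed cohorts). Attribute `method` records the
#'   computation path.
#' @export
loadDistribution <- function(state, arch, regime, resolution = NULL,
                             method = c("auto", "exact", "mc"),
                             nDraws = 1e5) {
  method <- match.arg(method)
  st <- sTildeOf(regime, arch)
  vals <- c(if (arch@LR > 0L) c(arch@h * arch@s, arch@s),
            if (arch@LA > 0L) st)
  d <- numericGcd(vals)
  commensurate <- d > 0 && d > max(vals) * 1e-6
  if (method == "auto") method <- if (commensurate) "exact" else "mc"
  if (method == "exact" && !commensurate)
    stop("load increments are not commensurate; use method = 'mc'")
  island <- regime@habitat == "island"
  # on the island the additive load counts "0" alleles: swap the roles of
  # p00 and p11 so the same convolution applies
  p01A <- state@p01A
  p11A <- if (island) 1 - state@p01A - state@p11A else state@p11A

  if (method == "exact") {
    n <- length(state@f)
    pmfs <- lapply(seq_len(n), function(i)
      cohortLoadPmf(p01A[i], p11A[i], state@p01R[i], state@p11R[i],
                    arch, st, d))
    maxIdx <- max(vapply(pmfs, function(x) x$off + length(x$p) - 1L,
                         integer(1)))
    acc <- function(idx) {
      tot <- numeric(maxIdx + 1L)
      wsum <- sum(state@f[idx])
      for (i in idx) {
        pm <- pmfs[[i]]
        j <- pm$off + seq_along(pm$p)
        tot[j] <- tot[j] + state@f[i] * pm$p
      }
      if (wsum > 0) tot / wsum else tot
    }
    pOut <- acc(1L)
    pSelf <- acc(seq_len(n)[-1L])
    f0 <- state@f[1]
    out <- data.frame(G = d * (0:maxIdx),
                      prob = f0 * pOut + (1 - f0) * pSelf,
                      probOutcrossed = pOut, probSelfed = pSelf)
    if (!is.null(resolution)) out <- rebinLoad(out, resolution)
    attr(out, "method") <- "exact"
    return(out)
  }

  # Monte Carlo: sample cohort, then multinomial counts per type
  idx <- sample.int(length(state@f), nDraws, replace = TRUE, prob = state@f)
  G <- numeric(nDraws)
  if (arch@LR > 0L) {
    n11 <- stats::rbinom(nDraws, arch@LR, state@p11R[idx])
    rest <- arch@LR - n11
    q01 <- state@p01R[idx] / pmax(1 - state@p11R[idx], 1e-300)
    n01 <- stats::rbinom(nDraws, rest, pmin(q01, 1))
    G <- G + arch@s * (n11 + arch@h * n01)
  }
  if (arch@LA > 0L && st > 0) {
    n11 <- stats::rbinom(nDraws, arch@LA, p11A[idx])
    rest <- arch@LA - n11
    q01 <- p01A[idx] / pmax(1 - p11A[idx], 1e-300)
    n01 <- stats::rbinom(nDraws, rest, pmin(q01, 1))
    G <- G + st * (2 * n11 + n01)
  }
  if (is.null(resolution)) resolution <- diff(range(G)) / 200
  if (resolution <= 0) resolution <- 1e-6
  br <- seq(0, max(G) + resolution, by = resolution)
  mid <- br[-1] - resolution / 2
  tab <- function(keep) {
    if (!any(keep)) return(numeric(length(mid)))
    h <- hist(G[keep], breaks = br, plot = FALSE)
    h$counts / sum(keep)
  }
  selfedDraw <- idx > 1L
  out <- data.frame(G = mid,
                    prob = tab(rep(TRUE, nDraws)),
                    probOutcrossed = tab(!selfedDraw),
                    probSelfed = tab(selfedDraw))
  attr(out, "method") <- "mc"
  out
}

rebinLoad <- function(df, width) {
  bin <- floor(df$G / width + 1e-9)
  agg <- function(v) as.numeric(tapply(v, bin, sum))
  ub <- sort(unique(bin))
  data.frame(G = (ub + 0.5) * width, prob = agg(df$prob),
             probOutcrossed = agg(df$probOutcrossed),
             probSelfed = agg(df$probSelfed))
}

#' Expected genetic load of a cohort state
#'
#' Exact mixture mean of the load distribution:
#' sum_i f_i [LR s (p11R + h p01R) + LA s~ (2 p11A + p01A)] (island: the
#' additive term counts "0" alleles).
#' @param state a census [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @export
expectedLoad <- function(state, arch, regime) {
  st <- sTildeOf(regime, arch)
  p11A <- if (regime@habitat == "island") 1 - state@p01A - state@p11A
          else state@p11A
  perCohort <- arch@LR * arch@s * (state@p11R + arch@h * state@p01R) +
    arch@LA * st * (2 * p11A + state@p01A)
  sum(state@f * perCohort)
}
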