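#' @include fitness.R
NULL

# Single-generation building blocks of the selfing-age-cohort (ILEC)
# recursion, written at the R level so each step can be inspected and
# tested; the equilibrium solver runs the same arithmetic in compiled code.

newCohortState <- function(f, p01A, p11A, p01R, p11R, rs,
                           converged = NA, iterations = 0, change = NA_real_) {
  new("CohortState", f = f, p01A = p01A, p11A = p11A, p01R = p01R,
      p11R = p11R, rs = rs, converged = as.logical(converged),
      iterations = as.numeric(iterations), change = as.numeric(change))
}

#' Initial cohort state
#'
#' Cohort masses start at the neutral selfing-age distribution
#' f_i = (1 - rs) rs^i (remaining geometric tail pooled into the absorbing
#' class); genotype frequencies start monomorphic for allele "0" unless
#' overridden. Equilibria are checked to be initialization-independent.
#'
#' @param rs selfing fraction in [0, 1].
#' @param IMax absorbing cohort-age cap (mass beyond is <= rs^IMax).
#' @param p01A,p11A,p01R,p11R optional starting genotype frequencies,
#'   recycled across cohorts.
#' @return A [CohortState-class].
#' @export
initialCohortState <- function(rs, IMax = 50, p01A = 0, p11A = 0,
                               p01R = 0, p11R = 0) {
  stopifnot(rs >= 0, rs <= 1, IMax >= 1)
  n <- IMax + 1L
  i <- 0:(IMax - 1L)
  f <- c((1 - rs) * rs^i, rs^IMax)
  f <- f / sum(f)
  z <- function(p) rep_len(as.numeric(p), n)
  newCohortState(f, z(p01A), z(p11A), z(p01R), z(p11R), rs)
}

# two-independent-flips genotype transition for one locus type
mutateGenotypeFreqs <- function(p01, p11, mu) {
  if (mu <= 0) return(list(p01 = p01, p11 = p11))
  a <- 1 - mu; b <- mu
  p00 <- 1 - p01 - p11
  list(p01 = p00 * 2 * a * b + p01 * (a^2 + b^2) + p11 * 2 * a * b,
       p11 = p00 * b^2 + p01 * a * b + p11 * a^2)
}

#' Cohort mutation step
#'
#' Applies the symmetric per-allele flip (rate muA or muR) to each cohort's
#' genotype frequencies: each of the two alleles flips independently, giving
#' the two-flip transition matrix on (p00, p01, p11). Cohort masses are
#' unchanged.
#'
#' @param state a [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @return The mutated [CohortState-class].
#' @export
cohortMutation <- function(state, arch) {
  a <- mutateGenotypeFreqs(state@p01A, state@p11A, arch@muA)
  r <- mutateGenotypeFreqs(state@p01R, state@p11R, arch@muR)
  newCohortState(state@f, a$p01, a$p11, r$p01, r$p11, state@rs)
}

genotypeWeights <- function(arch, regime) {
  st <- sTildeOf(regime, arch)
  list(A = if (regime@habitat == "source") c(1, exp(-st), exp(-2 * st))
           else c(exp(-2 * st), exp(-st), 1),
       R = c(1, exp(-arch@h * arch@s), exp(-arch@s)))
}

selectGenotypeFreqs <- function(p01, p11, w) {
  p00 <- 1 - p01 - p11
  nu <- p00 * w[1] + p01 * w[2] + p11 * w[3]
  list(p01 = p01 * w[2] / nu, p11 = p11 * w[3] / nu, nu = nu)
}

#' Cohort selection step
#'
#' Under within-cohort independence, selection factorizes across loci:
#' within each cohort the per-locus genotype frequencies are reweighted by
#' the marginal genotype weights (recessive: 1, e^{-hs}, e^{-s}; additive in
#' the source: 1, e^{-s0~}, e^{-2 s0~}; mirrored on the island), and the
#' cohort mean fitness is the product of per-locus normalizers,
#' wbar_i = nu_{i,A}^{LA} * nu_{i,R}^{LR}. Cohort masses are unchanged
#' (fitness reweighting happens in reproduction).
#'
#' @param state a [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @return list with elements `state` (post-selection [CohortState-class]),
#'   `wbar` (per-cohort mean fitness factors) and `logWbar` (their logs,
#'   accumulated in log space as LA*ln nu_A + LR*ln nu_R).
#' @export
cohortSelection <- function(state, arch, regime) {
  w <- genotypeWeights(arch, regime)
  a <- selectGenotypeFreqs(state@p01A, state@p11A, w$A)
  r <- selectGenotypeFreqs(state@p01R, state@p11R, w$R)
  logWbar <- arch@LA * log(a$nu) + arch@LR * log(r$nu)
  list(state = newCohortState(state@f, a$p01, a$p11, r$p01, r$p11, state@rs),
       wbar = exp(logWbar), logWbar = logWbar)
}

selfedGenotypeFreqs <- function(p01, p11)
  list(p01 = p01 / 2, p11 = p11 + p01 / 4)

reproduceGenotypeFreqs <- function(g, p01, p11, rs) {
  n <- length(g)
  q <- sum(g * (p11 + p01 / 2))         # pooled gamete allele frequency
  sf <- selfedGenotypeFreqs(p01, p11)
  n01 <- c(2 * q * (1 - q), sf$p01[-n])
  n11 <- c(q^2, sf$p11[-n])
  wa <- rs * g[n - 1]; wb <- rs * g[n]  # pool into the absorbing class
  if (wa + wb > 0) {
    n01[n] <- (wa * n01[n] + wb * sf$p01[n]) / (wa + wb)
    n11[n] <- (wa * n11[n] + wb * sf$p11[n]) / (wa + wb)
  } else {
    n01[n] <- sf$p01[n]; n11[n] <- sf$p11[n]
  }
  list(p01 = n01, p11 = n11)
}

#' Cohort reproduction step (partial selfing)
#'
#' Parents contribute with weights g_i proportional to f_i * wbar_i. The new
#' outcrossed cohort (selfing age 0, mass 1 - rs) is formed at Hardy-
#' Weinberg proportions from the pooled gamete allele frequency -- neglecting
#' within-cohort associations of outcrossed offspring is the defining
#' approximation. Selfed offspring of cohort i move to cohort i + 1 (mass
#' rs * g_i) with Mendelian selfing per locus (p11 -> p11 + p01/4,
#' p01 -> p01/2); ages at the cap are pooled into the absorbing class by
#' g-weighted averaging.
#'
#' @param state post-selection [CohortState-class].
#' @param wbar per-cohort mean fitness factors from [cohortSelection()].
#' @param rs selfing fraction in [0, 1].
#' @return The census [CohortState-class] of the offspring generation.
#' @export
cohortReproduction <- function(state, wbar, rs) {
  if (rs < 0 || rs > 1) stop("rs must be in [0, 1]")
  n <- length(state@f)
  g <- state@f * wbar
  g <- g / sum(g)
  f <- c(1 - rs, rs * g[-n])
  f[n] <- f[n] + rs * g[n]
  a <- reproduceGenotypeFreqs(g, state@p01A, state@p11A, rs)
  r <- reproduceGenotypeFreqs(g, state@p01R, state@p11R, rs)
  newCohortState(f, a$p01, a$p11, r$p01, r$p11, rs)
}

#' One full ILEC generation (mutation, selection, reproduction)
#'
#' @param state census [CohortState-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param rs selfing fraction.
#' @return The next census [CohortState-class].
#' @export
cohortGeneration <- function(state, arch, regime, rs = state@rs) {
  sel <- cohortSelection(cohortMutation(state, arch), arch, regime)
  cohortReproduction(sel$state, sel$wbar, rs)
}
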