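#' @include AllClasses.R
NULL

#' Construct genome architecture parameters
#'
#' The per-allele trait effect alpha is fixed to 1/LA, so the genome-wide
#' per-allele selection strength in the source is s0Tilde = beta0 * alpha.
#' Either `beta0` or `s0Tilde` may be given (the other is derived).
#'
#' @param LA,LR locus counts (nonnegative; at least one positive).
#' @param muA,muR per-locus per-generation allele flip probabilities.
#' @param s homozygous selective disadvantage at recessive loci.
#' @param h dominance coefficient of recessive alleles (0 <= h < 1/2).
#' @param beta0 selection gradient in the source habitat.
#' @param s0Tilde alternative parameterization: per-allele selection
#'   strength beta0 * alpha in the source.
#' @return An [ArchitectureParams-class] object.
#' @examples
#' arch <- architectureParams(LA = 1000, LR = 5000, muA = 1e-4, muR = 1e-4,
#'                            s = 0.05, h = 0.02, s0Tilde = 0.005)
#' s0Tilde(arch)
#' @export
architectureParams <- function(LA, LR, muA = 0, muR = 0, s = 0, h = 0,
                               beta0 = NULL, s0Tilde = NULL) {
  LA <- as.integer(LA); LR <- as.integer(LR)
  if (!is.null(beta0) && !is.null(s0Tilde))
    stop("give either beta0 or s0Tilde, not both")
  if (is.null(beta0)) {
    if (is.null(s0Tilde) || LA == 0L) beta0 <- 0
    else beta0 <- s0Tilde * LA  # s0Tilde / alpha with alpha = 1/LA
  }
  new("ArchitectureParams", LA = LA, LR = LR, muA = as.numeric(muA),
      muR = as.numeric(muR), s = as.numeric(s), h = as.numeric(h),
      beta0 = as.numeric(beta0))
}

#' Per-allele trait effect alpha = 1/LA
#'
#' Returns 0 for a genome without additive loci (the trait is then
#' identically zero).
#' @param arch an [ArchitectureParams-class].
#' @export
alphaEffect <- function(arch) if (arch@LA > 0L) 1 / arch@LA else 0

#' Per-allele selection strength in the source, s0Tilde = beta0 * alpha
#' @param arch an [ArchitectureParams-class].
#' @export
s0Tilde <- function(arch) arch@beta0 * alphaEffect(arch)

#' Genome-wide mutation rates U = 2 mu L
#' @param arch an [ArchitectureParams-class].
#' @return Named numeric c(A = 2*muA*LA, R = 2*muR*LR).
#' @export
genomicMutationRate <- function(arch)
  c(A = 2 * arch@muA * arch@LA, R = 2 * arch@muR * arch@LR)

#' Trait range endpoints
#' @param arch an [ArchitectureParams-class].
#' @return Named numeric c(zmin = -alpha*LA, zmax = alpha*LA).
#' @export
traitRange <- function(arch) {
  a <- alphaEffect(arch) * arch@LA
  c(zmin = -a, zmax = a)
}

#' Source-habitat selection regime
#'
#' Penalizes trait distance from zmin with gradient beta0 taken from the
#' architecture.
#' @param arch an [ArchitectureParams-class].
#' @export
sourceRegime <- function(arch) new("SelectionRegime", habitat = "source",
                                   beta = arch@beta0)

#' Island selection regime
#'
#' The direction of selection on the additive trait is reversed relative to
#' the source: the island penalizes distance from zmax with gradient beta1.
#' Either `beta1` or the per-allele strength `s1Tilde = beta1 * alpha` may
#' be given.
#' @param arch an [ArchitectureParams-class].
#' @param beta1 island selection gradient.
#' @param s1Tilde alternative parameterization (per-allele strength).
#' @export
islandRegime <- function(arch, beta1 = NULL, s1Tilde = NULL) {
  if (!is.null(beta1) && !is.null(s1Tilde))
    stop("give either beta1 or s1Tilde, not both")
  if (is.null(beta1)) {
    if (is.null(s1Tilde) || arch@LA == 0L) beta1 <- 0
    else beta1 <- s1Tilde * arch@LA
  }
  new("SelectionRegime", habitat = "island", beta = as.numeric(beta1))
}

#' Per-allele selection strength of a regime, beta * alpha
#' @param regime a [SelectionRegime-class].
#' @param arch an [ArchitectureParams-class].
#' @export
sTildeOf <- function(regime, arch) regime@beta * alphaEffect(arch)

#' Island demography parameters
#'
#' @param arch an [ArchitectureParams-class] (used to convert s1Tilde).
#' @param rs selfing probability on the island (same as the source).
#' @param beta1,s1Tilde island selection gradient (one of the two).
#' @param r0 intrinsic growth rate.
#' @param K carrying capacity.
#' @param N0 founder count.
#' @param Tgen success horizon in generations.
#' @param successFraction success threshold as a fraction of K.
#' @return An [IslandParams-class] object.
#' @export
islandParams <- function(arch, rs, beta1 = NULL, s1Tilde = NULL, r0 = 1.1,
                         K = 1000, N0 = 10, Tgen = 100,
                         successFraction = 0.1) {
  reg <- islandRegime(arch, beta1 = beta1, s1Tilde = s1Tilde)
  new("IslandParams", beta1 = reg@beta, r0 = as.numeric(r0),
      K = as.numeric(K), N0 = as.integer(N0), Tgen = as.integer(Tgen),
      successFraction = as.numeric(successFraction), rs = as.numeric(rs))
}
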