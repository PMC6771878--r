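#' @include AllGenerics.R
NULL

#' Genome architecture and selection constants
#'
#' Layout of the simulated genome: `LA` codominant ("additive") loci whose
#' alleles contribute -alpha/2 or +alpha/2 to a trait under directional
#' selection, and `LR` loci carrying partially recessive deleterious alleles.
#' All loci are unlinked and loci within a type are exchangeable. The
#' per-allele effect alpha is fixed to 1/LA by the usual quantitative
#' genetics convention, so the trait spans [-alpha*LA, +alpha*LA] = [-1, 1].
#'
#' @slot LA,LR integer locus counts (either may be zero).
#' @slot muA,muR per-locus, per-generation symmetric allele flip rates.
#' @slot s homozygous selective disadvantage at recessive loci.
#' @slot h dominance coefficient of recessive alleles, 0 <= h < 1/2.
#' @slot beta0 directional selection gradient in the source habitat.
#' @export
setClass("ArchitectureParams",
  representation(LA = "integer", LR = "integer", muA = "numeric",
                 muR = "numeric", s = "numeric", h = "numeric",
                 beta0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@LA < 0L || object@LR < 0L)
      msg <- c(msg, "LA and LR must be nonnegative")
    if (object@LA + object@LR < 1L)
      msg <- c(msg, "at least one locus is required")
    for (nm in c("muA", "muR")) {
      v <- slot(object, nm)
      if (length(v) != 1L || is.na(v) || v < 0 || v > 0.5)
        msg <- c(msg, sprintf("%s must be a single rate in [0, 0.5]", nm))
    }
    if (object@s < 0) msg <- c(msg, "s must be >= 0")
    if (object@h < 0 || object@h >= 0.5)
      msg <- c(msg, "h must satisfy 0 <= h < 0.5")
    if (object@beta0 < 0) msg <- c(msg, "beta0 must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Selection regime (habitat)
#'
#' Directional selection on the additive trait: the source habitat penalizes
#' distance from zmin (exponent beta * (z - zmin)), the island penalizes
#' distance from zmax (exponent beta * (zmax - z)). Recessive deleterious
#' alleles are penalized identically in both habitats.
#'
#' @slot habitat `"source"` or `"island"`.
#' @slot beta nonnegative selection gradient (beta0 or beta1).
#' @export
setClass("SelectionRegime",
  representation(habitat = "character", beta = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@habitat %in% c("source", "island"))
      msg <- c(msg, "habitat must be 'source' or 'island'")
    if (length(object@beta) != 1L || is.na(object@beta) || object@beta < 0)
      msg <- c(msg, "beta must be a single nonnegative number")
    if (length(msg)) msg else TRUE
  })

#' Selfing-age cohort state (ILEC)
#'
#' State of the deterministic cohort approximation: the mass `f[i+1]` of
#' individuals with selfing age i (the final class is absorbing), and the
#' per-cohort frequencies of heterozygous (`p01`) and "11"-homozygous
#' (`p11`) loci for each locus type. Loci within a type are exchangeable so
#' one number per cohort per type suffices.
#'
#' @slot f cohort mass vector, summing to one.
#' @slot p01A,p11A,p01R,p11R per-cohort genotype frequencies by locus type.
#' @slot rs selfing fraction the state was computed for.
#' @slot converged logical; whether the equilibrium iteration converged.
#' @slot iterations number of generations iterated.
#' @slot change final sup-norm change between successive generations.
#' @export
setClass("CohortState",
  representation(f = "numeric", p01A = "numeric", p11A = "numeric",
                 p01R = "numeric", p11R = "numeric", rs = "numeric",
                 converged = "logical", iterations = "numeric",
                 change = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@f)
    if (n < 2L) msg <- c(msg, "need at least two cohort classes")
    for (nm in c("p01A", "p11A", "p01R", "p11R"))
      if (length(slot(object, nm)) != n)
        msg <- c(msg, sprintf("%s must have the same length as f", nm))
    if (any(object@f < -1e-12))
      msg <- c(msg, "cohort masses must be nonnegative")
    if (abs(sum(object@f) - 1) > 1e-8)
      msg <- c(msg, "cohort masses must sum to 1")
    ok <- function(p01, p11) all(p01 > -1e-12 & p11 > -1e-12 &
                                   p01 + p11 < 1 + 1e-12)
    if (!ok(object@p01A, object@p11A) || !ok(object@p01R, object@p11R))
      msg <- c(msg, "genotype frequencies must lie in the simplex")
    if (object@rs < 0 || object@rs > 1)
      msg <- c(msg, "rs must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Explicit diploid population
#'
#' Genotypes stored as two phased haplotype matrices of 0/1 bytes, loci in
#' rows (additive block first, then recessive block), individuals in
#' columns. Phase is kept so gamete formation under free recombination is
#' exact. `selfingAge` and `selfed` are bookkeeping from the most recent
#' round of reproduction.
#'
#' @slot hap1,hap2 raw matrices (loci x individuals) of 0/1 bytes.
#' @slot selfingAge integer vector; generations of continuous selfing in
#'   each individual's lineage (0 for outcrossed offspring).
#' @slot selfed logical; whether each individual was produced by a selfing
#'   decision in the last reproduction round.
#' @slot generation integer generation counter.
#' @export
setClass("DiploidPopulation",
  representation(hap1 = "matrix", hap2 = "matrix", selfingAge = "integer",
                 selfed = "logical", generation = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.raw(object@hap1) || !is.raw(object@hap2))
      msg <- c(msg, "haplotypes must be raw matrices")
    if (!identical(dim(object@hap1), dim(object@hap2)))
      msg <- c(msg, "haplotype matrices must have identical dimensions")
    n <- ncol(object@hap1)
    if (n < 1L) msg <- c(msg, "population must contain at least 1 individual")
    if (length(object@selfingAge) != n || length(object@selfed) != n)
      msg <- c(msg, "selfingAge and selfed must have one entry per individual")
    if (length(msg) == 0L && any(object@hap1 > as.raw(1L)))
      msg <- c(msg, "haplotype entries must be 0 or 1")
    if (length(msg)) msg else TRUE
  })

#' Island demography and habitat parameters
#'
#' @slot beta1 selection gradient on the island (favoring high trait values).
#' @slot r0 intrinsic growth rate.
#' @slot K carrying capacity (Inf allowed).
#' @slot N0 founder count.
#' @slot Tgen horizon in generations for the success criterion.
#' @slot successFraction threshold fraction of K defining success.
#' @slot rs selfing probability on the island (same as in the source).
#' @export
setClass("IslandParams",
  representation(beta1 = "numeric", r0 = "numeric", K = "numeric",
                 N0 = "integer", Tgen = "integer",
                 successFraction = "numeric", rs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@beta1 < 0) msg <- c(msg, "beta1 must be >= 0")
    if (object@K < 1) msg <- c(msg, "K must be >= 1")
    if (object@N0 < 1L) msg <- c(msg, "N0 must be >= 1")
    if (object@Tgen < 1L) msg <- c(msg, "Tgen must be >= 1")
    if (object@successFraction <= 0 || object@successFraction > 1)
      msg <- c(msg, "successFraction must be in (0, 1]")
    if (object@rs < 0 || object@rs > 1) msg <- c(msg, "rs must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Population summary statistics
#'
#' Common container for the quantities compared between the cohort
#' approximation and individual-based simulation: allele frequencies, mean
#' fitness, inbreeding depression, pairwise identity disequilibria, gametic
#' LD and heterozygosity. Simulation-derived objects carry standard errors
#' and the per-sample records.
#'
#' @slot values named numeric vector of point estimates.
#' @slot se named numeric vector of standard errors (empty for deterministic
#'   predictions).
#' @slot nSamples number of stationary samples averaged (simulation only).
#' @slot source `"ilec"` or `"simulation"`.
#' @slot samples per-sample records (data.frame) or NULL.
#' @slot loadHist load histogram (data.frame) or NULL.
#' @export
setClass("SummaryStats",
  representation(values = "numeric", se = "numeric", nSamples = "integer",
                 source = "character", samples = "ANY", loadHist = "ANY"))

#' Establishment experiment result
#'
#' @slot success logical vector of per-replicate outcomes.
#' @slot pEst estimated establishment probability.
#' @slot se binomial standard error sqrt(p(1-p)/R).
#' @slot trajectories list of per-replicate population-size trajectories.
#' @slot wbarTrajectories list of per-replicate mean-fitness trajectories.
#' @slot sfs matrix of adaptive-allele frequencies (replicates x loci) taken
#'   at the requested snapshot generation, or NULL.
#' @slot params echo of the run configuration.
#' @slot seed master seed used (or NA).
#' @export
setClass("EstablishmentResult",
  representation(success = "logical", pEst = "numeric", se = "numeric",
                 trajectories = "list", wbarTrajectories = "list",
                 sfs = "ANY", params = "list", seed = "ANY"),
  validity = function(object) {
    if (length(object@pEst) == 1L &&
        (object@pEst < 0 || object@pEst > 1))
      "pEst must be in [0, 1]" else TRUE
  })
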