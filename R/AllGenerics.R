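#' @include RcppExports.R
NULL

#' Population-wide allele frequency
#'
#' Frequency of the "1" allele (deleterious at recessive loci, disfavored in
#' the source at additive loci), either predicted by the cohort model or
#' counted from an explicit population.
#'
#' @param x a [CohortState-class] or [DiploidPopulation-class].
#' @param ... further arguments passed to methods (a `DiploidPopulation`
#'   needs the [ArchitectureParams-class] to split the genome into blocks).
#' @return Named numeric vector with elements `A` and `R` (NA for a locus
#'   type with zero loci).
#' @export
setGeneric("alleleFrequency", function(x, ...) standardGeneric("alleleFrequency"))

#' Mean fitness
#'
#' @param x object to compute or extract mean fitness from.
#' @param ... passed to methods.
#' @export
setGeneric("meanFitness", function(x, ...) standardGeneric("meanFitness"))

#' Inbreeding depression
#'
#' delta = 1 - Wbar_self / Wbar_oc, the relative fitness deficit of selfed
#' versus outcrossed individuals at census. NA when the population contains
#' no selfed (or no outcrossed) class.
#'
#' @param x object to extract inbreeding depression from.
#' @param ... passed to methods.
#' @export
setGeneric("inbreedingDepression", function(x, ...) standardGeneric("inbreedingDepression"))

#' Number of individuals in a population
#' @param x a [DiploidPopulation-class].
#' @export
setGeneric("populationSize", function(x) standardGeneric("populationSize"))

#' Selfing-age cohort masses
#' @param x a [CohortState-class].
#' @return Numeric vector `f`, with element i+1 the mass of selfing age i;
#'   the final class is absorbing.
#' @export
setGeneric("cohortMasses", function(x) standardGeneric("cohortMasses"))

#' Establishment probability estimate
#' @param x an [EstablishmentResult-class].
#' @return Named numeric c(pEst = ..., se = ...).
#' @export
setGeneric("pEstimate", function(x) standardGeneric("pEstimate"))

#' Additive trait value
#'
#' Sum of allelic contributions (-alpha/2 or +alpha/2) over additive loci;
#' recessive loci do not contribute.
#'
#' @param x a [DiploidPopulation-class].
#' @param arch an [ArchitectureParams-class].
#' @param ... passed to methods.
#' @return Numeric vector of trait values z in [zmin, zmax].
#' @export
setGeneric("traitValue", function(x, arch, ...) standardGeneric("traitValue"))

#' Individual fitness
#'
#' Multiplicative fitness W = exp(-G) under the given selection regime.
#'
#' @param x a [DiploidPopulation-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param ... passed to methods.
#' @return Numeric vector of fitnesses in (0, 1].
#' @export
setGeneric("individualFitness", function(x, arch, regime, ...)
  standardGeneric("individualFitness"))

#' Genetic load
#'
#' Negative log fitness G = -ln(W), decomposable into an additive-trait
#' (maladaptation) component and a deleterious-recessive component.
#'
#' @param x a [DiploidPopulation-class].
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class].
#' @param component one of "total", "additive", "recessive".
#' @param ... passed to methods.
#' @export
setGeneric("geneticLoad", function(x, arch, regime, component = "total", ...)
  standardGeneric("geneticLoad"))
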