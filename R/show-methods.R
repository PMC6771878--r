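#' @include experiment.R
NULL

#' @importFrom methods show is new slot validObject
NULL

setMethod("show", "ArchitectureParams", function(object) {
  U <- genomicMutationRate(object)
  cat("ArchitectureParams\n")
  cat(sprintf("  additive : LA = %d, muA = %g (UA = %g), s0~ = %g\n",
              object@LA, object@muA, U["A"], s0Tilde(object)))
  cat(sprintf("  recessive: LR = %d, muR = %g (UR = %g), s = %g, h = %g\n",
              object@LR, object@muR, U["R"], object@s, object@h))
})

setMethod("show", "SelectionRegime", function(object) {
  cat(sprintf("SelectionRegime: %s habitat, beta = %g\n", object@habitat,
              object@beta))
})

setMethod("show", "CohortState", function(object) {
  p <- alleleFrequency(object)
  cat(sprintf("CohortState (%d cohort classes, rs = %g)\n",
              length(object@f), object@rs))
  cat(sprintf("  converged: %s after %g generations (change %.3g)\n",
              object@converged, object@iterations, object@change))
  cat(sprintf("  outcrossed mass f0 = %.4f; allele freq A = %.5g, R = %.5g\n",
              object@f[1], p["A"], p["R"]))
})

setMethod("show", "DiploidPopulation", function(object) {
  cat(sprintf("DiploidPopulation: %d individuals x %d loci (generation %d)\n",
              ncol(object@hap1), nrow(object@hap1), object@generation))
  if (any(object@selfed))
    cat(sprintf("  realized selfing fraction last generation: %.3f\n",
                mean(object@selfed)))
})

setMethod("show", "IslandParams", function(object) {
  cat(sprintf(
    "IslandParams: beta1 = %g, r0 = %g, K = %g, N0 = %d, T = %d, rs = %g\n",
    object@beta1, object@r0, object@K, object@N0, object@Tgen, object@rs))
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats [%s]\n", object@source))
  v <- object@values
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.5g", x))
  cat(sprintf("  pA = %s, pR = %s, Wbar = %s, delta = %s\n",
              fmt(v["pA"]), fmt(v["pR"]), fmt(v["meanFitness"]),
              fmt(v["delta"])))
  cat(sprintf("  ID: AA = %s, RR = %s, AR = %s\n",
              fmt(v["idAA"]), fmt(v["idRR"]), fmt(v["idAR"])))
  if (object@nSamples > 1L)
    cat(sprintf("  averaged over %d stationary samples\n", object@nSamples))
})

setMethod("show", "EstablishmentResult", function(object) {
  cat(sprintf(
    "EstablishmentResult: P_est = %.4f +/- %.4f (%d replicates)\n",
    object@pEst, object@se, length(object@success)))
})
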