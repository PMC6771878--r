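#' @include ilec-steps.R
NULL

#' Solver settings for the cohort equilibrium
#'
#' @param IMax absorbing cohort-age cap; mass beyond age IMax (at most
#'   rs^IMax) is pooled into the final class.
#' @param tol convergence tolerance: sup-norm change of the full state
#'   between successive generations.
#' @param maxIter iteration cap.
#' @return A classed list of solver settings.
#' @export
ilecSolverParams <- function(IMax = 50, tol = 1e-12, maxIter = 1e6) {
  stopifnot(IMax >= 1, tol > 0, maxIter >= 1)
  structure(list(IMax = as.integer(IMax), tol = tol, maxIter = maxIter),
            class = "IlecSolverParams")
}

#' Deterministic mutation-selection equilibrium of the cohort model
#'
#' Iterates the cohort recursion (mutation, selection, partial-selfing
#' reproduction) until the sup-norm change between successive census states
#' falls below `solver$tol`. The census is taken after reproduction.
#'
#' @param arch an [ArchitectureParams-class].
#' @param regime a [SelectionRegime-class]; use [sourceRegime()] for the
#'   source population.
#' @param rs selfing fraction in [0, 1].
#' @param solver settings from [ilecSolverParams()].
#' @param init optional starting [CohortState-class] (defaults to
#'   [initialCohortState()]; equilibria are initialization-independent).
#' @param onNonConvergence `"warn"` returns the last state flagged
#'   unconverged; `"error"` stops.
#' @return A converged [CohortState-class] (check `isConverged()`), carrying
#'   the iteration count and final change.
#' @examples
#' arch <- architectureParams(LA = 100, LR = 0, muA = 1e-4, s0Tilde = 0.005)
#' eq <- ilecEquilibrium(arch, sourceRegime(arch), rs = 0.5)
#' alleleFrequency(eq)
#' @export
ilecEquilibrium <- function(arch, regime, rs, solver = ilecSolverParams(),
                            init = NULL,
                            onNonConvergence = c("warn", "error")) {
  onNonConvergence <- match.arg(onNonConvergence)
  stopifnot(rs >= 0, rs <= 1)
  if (is.null(init)) init <- initialCohortState(rs, IMax = solver$IMax)
  res <- cpp_ilec_solve(init@f, init@p01A, init@p11A, init@p01R, init@p11R,
                        arch@LA, arch@LR, arch@muA, arch@muR, arch@s,
                        arch@h, sTildeOf(regime, arch),
                        regime@habitat == "island", rs,
                        solver$tol, solver$maxIter)
  st <- newCohortState(res$f, res$p01A, res$p11A, res$p01R, res$p11R, rs,
                       converged = res$converged, iterations = res$iterations,
                       change = res$change)
  if (!res$converged) {
    msg <- sprintf(
      "ILEC iteration did not converge in %g generations (change %.3g > tol %.3g)",
      res$iterations, res$change, solver$tol)
    if (onNonConvergence == "error") stop(msg)
    warning(msg)
  }
  st
}

#' Has the equilibrium iteration converged?
#' @param state a [CohortState-class].
#' @export
isConverged <- function(state) isTRUE(state@converged)

#' @describeIn cohortMasses cohort mass vector of a state.
#' @export
setMethod("cohortMasses", "CohortState", function(x) x@f)

#' @describeIn alleleFrequency mixture allele frequency
#'   p = sum_i f_i (p11(i) + p01(i)/2) per locus type. Types without loci in
#'   the architecture are still reported (the state does not know the locus
#'   counts); mask with the architecture if needed.
#' @export
setMethod("alleleFrequency", "CohortState", function(x, ...)
  c(A = sum(x@f * (x@p11A + x@p01A / 2)),
    R = sum(x@f * (x@p11R + x@p01R / 2))))
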