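# Independent single-population oracle: deterministic one-locus genotype
# recursion (mutation -> selection -> mating) used to cross-check the
# cohort solver in the rs = 0 (single cohort, random mating) and rs = 1
# (pure selfing) limits. Written independently of the package internals.

oracleMutate <- function(p, mu) {
  # p = c(p00, p01, p11); two independent allele flips
  M <- matrix(c((1 - mu)^2, 2 * mu * (1 - mu), mu^2,
                mu * (1 - mu), (1 - mu)^2 + mu^2, mu * (1 - mu),
                mu^2, 2 * mu * (1 - mu), (1 - mu)^2),
              nrow = 3, byrow = TRUE)
  as.numeric(t(M) %*% p)
}

oracleSelect <- function(p, w) {
  pw <- p * w
  pw / sum(pw)
}

oracleRandomMating <- function(p) {
  q <- p[3] + p[2] / 2
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

oracleSelfing <- function(p) {
  c(p[1] + p[2] / 4, p[2] / 2, p[3] + p[2] / 4)
}

# iterate to fixed point; mating = "random" or "selfing"
oracleEquilibrium <- function(mu, w, mating = "random", tol = 1e-14,
                              maxIter = 2e6) {
  p <- c(1, 0, 0)
  for (i in seq_len(maxIter)) {
    pn <- oracleMutate(p, mu)
    pn <- oracleSelect(pn, w)
    pn <- if (mating == "random") oracleRandomMating(pn) else oracleSelfing(pn)
    if (max(abs(pn - p)) < tol) return(pn)
    p <- pn
  }
  stop("oracle did not converge")
}

recessiveWeights <- function(s, h) c(1, exp(-h * s), exp(-s))
additiveSourceWeights <- function(s0) c(1, exp(-s0), exp(-2 * s0))

# tiny architectures shared across tests
archRec <- function(LR = 50, muR = 1e-3, s = 0.05, h = 0.1)
  architectureParams(LA = 0, LR = LR, muR = muR, s = s, h = h)

archAdd <- function(LA = 50, muA = 1e-3, s0 = 0.005)
  architectureParams(LA = LA, LR = 0, muA = muA, s0Tilde = s0)

archBoth <- function(LA = 20, LR = 40, muA = 1e-3, muR = 1e-3, s = 0.05,
                     h = 0.1, s0 = 0.005)
  architectureParams(LA = LA, LR = LR, muA = muA, muR = muR, s = s, h = h,
                     s0Tilde = s0)
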