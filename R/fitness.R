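#' @include architecture.R
NULL

intHaps <- function(pop) {
  L <- nrow(pop@hap1)
  list(h1 = matrix(as.integer(pop@hap1), nrow = L),
       h2 = matrix(as.integer(pop@hap2), nrow = L))
}

checkGenomeLength <- function(pop, arch) {
  if (nrow(pop@hap1) != arch@LA + arch@LR)
    stop("genome length (", nrow(pop@hap1),
         ") does not match architecture LA + LR = ", arch@LA + arch@LR)
}

# per-individual counts used by both fitness and load
genotypeCounts <- function(pop, arch) {
  checkGenomeLength(pop, arch)
  hp <- intHaps(pop)
  LA <- arch@LA
  g <- hp$h1 + hp$h2
  if (LA > 0L) {
    nAdd <- colSums(g[seq_len(LA), , drop = FALSE])
  } else nAdd <- numeric(ncol(g))
  if (arch@LR > 0L) {
    gr <- g[LA + seq_len(arch@LR), , drop = FALSE]
    nHom <- colSums(gr == 2L)
    nHet <- colSums(gr == 1L)
  } else nHom <- nHet <- numeric(ncol(g))
  list(nAdd = nAdd, nHom = nHom, nHet = nHet)
}

#' @describeIn traitValue trait values of all individuals: z = zmin +
#'   alpha * (number of "1" alleles at additive loci).
#' @export
setMethod("traitValue", "DiploidPopulation", function(x, arch, ...) {
  cnt <- genotypeCounts(x, arch)
  unname(traitRange(arch)["zmin"] + alphaEffect(arch) * cnt$nAdd)
})

loadComponents <- function(pop, arch, regime) {
  cnt <- genotypeCounts(pop, arch)
  st <- sTildeOf(regime, arch)
  add <- if (regime@habitat == "source") st * cnt$nAdd
         else st * (2 * arch@LA - cnt$nAdd)
  rec <- arch@s * (cnt$nHom + arch@h * cnt$nHet)
  list(additive = add, recessive = rec)
}

#' @describeIn individualFitness fitness of all individuals in a population.
#' @export
setMethod("individualFitness", "DiploidPopulation",
  function(x, arch, regime, ...) {
    lc <- loadComponents(x, arch, regime)
    exp(-(lc$additive + lc$recessive))
  })

#' @describeIn geneticLoad load G = -ln W of all individuals, or one of its
#'   two components.
#' @export
setMethod("geneticLoad", "DiploidPopulation",
  function(x, arch, regime, component = "total", ...) {
    component <- match.arg(component, c("total", "additive", "recessive"))
    lc <- loadComponents(x, arch, regime)
    switch(component,
           total = lc$additive + lc$recessive,
           additive = lc$additive,
           recessive = lc$recessive)
  })

#' Assemble a population from explicit haplotype matrices
#'
#' Convenience constructor for small hand-built populations (mainly for
#' examples and tests). Matrices are loci x individuals with 0/1 entries;
#' the additive block comes first.
#'
#' @param hap1,hap2 integer/numeric 0-1 matrices, loci x individuals.
#' @param selfingAge optional integer vector (defaults to 0).
#' @return A [DiploidPopulation-class].
#' @export
makePopulation <- function(hap1, hap2, selfingAge = NULL) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  stopifnot(identical(dim(hap1), dim(hap2)),
            all(hap1 %in% 0:1), all(hap2 %in% 0:1))
  n <- ncol(hap1)
  if (is.null(selfingAge)) selfingAge <- integer(n)
  r1 <- matrix(as.raw(hap1), nrow = nrow(hap1))
  r2 <- matrix(as.raw(hap2), nrow = nrow(hap2))
  new("DiploidPopulation", hap1 = r1, hap2 = r2,
      selfingAge = as.integer(selfingAge), selfed = logical(n),
      generation = 0L)
}

#' @describeIn populationSize number of individuals (columns).
#' @export
setMethod("populationSize", "DiploidPopulation", function(x) ncol(x@hap1))

#' @describeIn alleleFrequency observed "1"-allele frequency per locus type;
#'   pass `arch` to delimit the additive and recessive blocks.
#' @export
setMethod("alleleFrequency", "DiploidPopulation", function(x, arch, ...) {
  checkGenomeLength(x, arch)
  hp <- intHaps(x)
  g <- hp$h1 + hp$h2
  n2 <- 2 * ncol(g)
  pA <- if (arch@LA > 0L) sum(g[seq_len(arch@LA), , drop = FALSE]) /
          (n2 * arch@LA) else NA_real_
  pR <- if (arch@LR > 0L)
          sum(g[arch@LA + seq_len(arch@LR), , drop = FALSE]) /
            (n2 * arch@LR) else NA_real_
  c(A = pA, R = pR)
})

#' @describeIn meanFitness mean fitness of a population under a regime.
#' @export
setMethod("meanFitness", "DiploidPopulation", function(x, arch, regime, ...)
  mean(individualFitness(x, arch, regime)))
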