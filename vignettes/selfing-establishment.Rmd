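---
title: "Models and methods: partial selfing, polygenic load, and establishment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: partial selfing, polygenic load, and establishment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfEstab)
```

# The biological problem

A large, partially selfing hermaphroditic population (the "source", e.g. a
mainland plant population) sits at mutation-selection balance. Some of its
genetic load is due to partially recessive deleterious alleles; some is due
to maladaptation of a polygenic trait under directional selection. When a
handful of founders from this population colonize a new habitat where the
direction of selection on the trait is reversed and population growth is
governed by hard selection, two forces decide their fate: the inbreeding
load exposed by the small-population phase, and the capacity to adapt from
standing variation. `selfEstab` provides the three pieces needed to study
this question quantitatively: a deterministic cohort model of the source, a
forward simulator that validates it, and an establishment simulator.

# Genome and fitness model

Each diploid genome carries `LA` unlinked codominant ("additive") loci and
`LR` unlinked partially recessive loci; there is no epistasis and no
linkage. Alleles at additive loci contribute $-\alpha/2$ or $+\alpha/2$ to
a trait $z$, with $\alpha = 1/L_A$, so $z \in [z_{min}, z_{max}] = [-1, 1]$.
Fitness is multiplicative across loci:

$$W = \exp\Big[-\beta_0 (z - z_{min}) - s \sum_{i=1}^{L_R} (X_i + h Y_i)\Big]$$

in the source, where $X_i, Y_i$ indicate homozygosity/heterozygosity for
the deleterious allele at recessive locus $i$, $s$ is the homozygous
selective disadvantage and $h < 1/2$ the dominance coefficient. The island
regime replaces $\beta_0 (z - z_{min})$ by $\beta_1 (z_{max} - z)$: the
trait allele written "1", disfavored in the source, is favored on the
island, while recessive deleterious alleles are penalized identically in
both habitats. The per-allele strengths $\tilde s_0 = \beta_0 \alpha$ and
$\tilde s_1 = \beta_1 \alpha$ are the natural parameters and are accepted
directly by the constructors. Genetic load is $G = -\ln W$, the sum of an
additive-maladaptation and a recessive component.

The life cycle is mutation (symmetric per-allele flips at rates
$\mu_A, \mu_R$), selection, then reproduction in which a fraction $r_s$ of
offspring are produced by selfing. Genomes are stored phased, so gamete
formation under free recombination is exact.

# The cohort approximation (ILEC)

Partial selfing generates population-wide identity disequilibrium (ID) and
linkage disequilibrium even among unlinked, non-epistatic loci, because
individuals differ in their recent selfing history. Following the
inbreeding-history view, individuals are classified by *selfing age* — the
number of consecutive selfed generations back to the last outcrossing
event. The approximation implemented here assumes *identity and linkage
equilibrium within cohorts*: loci are treated as statistically independent
within each selfing-age class, so all population-wide disequilibria arise
from differences between cohorts. The state is then just the cohort masses
$f_i$ and per-cohort genotype frequencies $p_{01,t}(i)$, $p_{11,t}(i)$ for
each locus type $t \in \{A, R\}$.

One generation consists of:

* **Mutation** — each of the two alleles flips independently with
  probability $\mu$, a 3x3 transition on $(p_{00}, p_{01}, p_{11})$.
* **Selection** — under within-cohort independence, selection factorizes:
  per-locus genotype frequencies are reweighted by the marginal genotype
  weights ($1, e^{-hs}, e^{-s}$ at recessive loci; $1, e^{-\tilde s_0},
  e^{-2\tilde s_0}$ at additive loci in the source, mirrored on the
  island), and the cohort mean fitness is the product of per-locus
  normalizers, $\bar w_i = \nu_{i,A}^{L_A} \nu_{i,R}^{L_R}$, accumulated in
  log space so $L \sim 5000$ cannot underflow.
* **Reproduction** — parents contribute with weights
  $g_i \propto f_i \bar w_i$. Outcrossed offspring (mass $1 - r_s$) form
  the new age-0 cohort at Hardy-Weinberg proportions of the pooled gamete
  frequency; neglecting the associations among the outcrossed offspring of
  heterogeneous parents is the defining approximation. Selfed offspring of
  cohort $i$ move to cohort $i+1$ (mass $r_s g_i$) with per-locus Mendelian
  selfing, $p_{11} \to p_{11} + p_{01}/4$, $p_{01} \to p_{01}/2$.

These recursions are iterated to a fixed point (`ilecEquilibrium()`). The
exact update equations are not spelled out in closed form anywhere we
could copy them from; the factorized form above is the one forced by the
two stated assumptions (within-cohort independence, multiplicative
fitness), and its validation is the agreement with individual-based
simulation that the test suite checks.

Derived quantities: allele frequencies are cohort mixtures; pairwise ID
between two loci is the between-cohort variance (same-type pair) or
covariance (additive-recessive pair) of the homozygote frequency,
normalized by $p^2 (1-p)^2$ — for a mixed pair we use
$p_A(1-p_A)\,p_R(1-p_R)$, the natural generalization to nonidentical loci,
which reduces to the same-type form for identical loci. Inbreeding
depression is $\delta = 1 - \bar W_{self}/\bar W_{oc}$ at census, with
"selfed" meaning every cohort of age $\ge 1$ weighted by census masses
(`delta` is reported absent at $r_s = 0$, where no selfed class exists).
The full load distribution is computed per cohort by exact convolution of
the multinomial per-type counts on a common load grid whenever the load
increments $hs$, $s$, $\tilde s$ are commensurate (binary-powering FFT
convolutions with tail trimming at $10^{-15}$), with a seeded Monte-Carlo
multinomial fallback otherwise.

## Numerical choices

* Cohort ages are capped at `IMax = 50` with an absorbing final class
  pooled by $g$-weighted averaging; the mass beyond the cap is at most
  $r_s^{50}$, far below the solver tolerance for $r_s \le 0.95$.
* Convergence: sup-norm change of the full state below `tol = 1e-12`
  between successive generations, `maxIter = 1e6`; non-convergence is
  reported (warning or error), never silently ignored. Note the distance
  to the fixed point can exceed `tol` by the relaxation time (roughly the
  inverse of the smallest effective selection rate), which is why the
  initialization-independence test solves at `1e-14`.
* Initialization: monomorphic for the favorable allele with the neutral
  age distribution $f_i \propto (1-r_s) r_s^i$; equilibria are checked to
  be initialization-independent.
* The neutral ID reference is evaluated from the exact selfing-age
  decomposition under neutrality (heterozygosity halves per selfing
  generation; outcrossed offspring at Hardy-Weinberg proportions), which
  collapses to $\sum_{j<i} f_i f_j (2^{-i} - 2^{-j})^2$, independent of
  allele frequency.

# The individual-based simulator

`generationStep()` implements the same life cycle on explicit genomes:
sparse symmetric mutation, fitness-weighted parent sampling with
replacement (cumulative-weight inversion), a selfing decision per
offspring, and free-recombination gametes. The compiled core draws all
randomness from R's generator, so `set.seed()` makes trajectories
bit-reproducible. Statistics are measured at the end of a generation on
the offspring: allele frequencies by counting; ID and gametic LD on a
random subsample of at most 2000 locus pairs per type pair (monomorphic
loci excluded, exhaustive enumeration when fewer pairs exist); $\delta$
from the realized selfing labels of the current offspring generation.
`runToStationarity()` averages such samples after burn-in and attaches
lag-1-autocorrelation-corrected standard errors, since consecutive samples
a few dozen generations apart are strongly correlated at weak selection.

The simulator is the package's referee for the cohort model. The
comparison harness (`compareIlecVsSim()`) flags a quantity when the
deviation exceeds

$$1.5 \times (3\,\mathrm{SE} + a_q),$$

a combined tolerance whose systematic allowance $a_q$ acknowledges that
the cohort model is an approximation and that a finite simulated
population drifts: 10% relative for allele frequencies, 5% relative for
mean fitness (plus a 0.005 absolute floor in the generic harness). The
acceptance-grade comparison at the reduced validation point (N = 2000,
$L_A = 200$, $L_R = 1000$, $\mu = 10^{-4}$, $s = 0.05$,
$\tilde s_0 = 0.005$, $h \in \{0.1, 0.02\}$, $r_s \in \{0, 0.2, 0.5,
0.8\}$) uses allowances fixed in advance of the same form: 10% relative
for frequencies, 5% + 0.01 for $\bar W$, 0.07 absolute for $\delta$, and
15% + 0.015 for ID. These are accuracy claims about the approximation at
this scale, not fitted constants; where the approximation is known to
degrade (nearly recessive alleles with $U_R/hs \gg 1$ at low $r_s$, and
any $r_s$ close to 1) deviations concentrate exactly where the theory
predicts.

Problem sizes for routine validation were chosen so the whole suite runs
comfortably on one core: the validation grid uses N = 2000 with a
5000-generation budget per grid point (burn-in 4500, 10 samples 50
generations apart), about an order of magnitude below the population size
a production study would use. What passing shows is that the deterministic
recursion tracks a finite but reasonably large population; it does not
show anything about regimes the generator does not emulate — real genomes
with linkage, unequal locus effects, epistasis, or selfing fractions
above 0.95, where reduced effective size and Hill-Robertson interference
invalidate the deterministic treatment entirely.

# Establishment in the new habitat

Founders are drawn from the equilibrium cohort state: each founder gets a
selfing age with probability $f_i$ and then independent per-locus
genotypes from its cohort's frequencies (phase randomized). The island
generation is mutation, island-regime fitness, then hard selection: the
offspring number is Poisson with mean

$$N_t\, e^{r_0 (1 - N_t/K)}\, \bar W_t,$$

the Ricker form. The density factor is written without the $N_t$
multiplier in some verbal descriptions of such models, but the per-capita
growth condition $e^{r_0} \bar W \gtrless 1$ and the role of $K$ as a
carrying capacity force the Ricker reading, which is what we implement.
Each offspring selfs with probability $r_s$ (island selfing equals source
selfing; no mating-system evolution) or outcrosses with independently
drawn, possibly identical parents — so the realized selfing fraction
inflates at small $N$ and equals 1 for a lone survivor, a deliberate
feature (no self-incompatibility in this version). Establishment succeeds
if $N$ at generation $T = 100$ is at least $K/10$; extinction
short-circuits. There is no migration after the founding event.

`estimateEstablishmentProbability()` runs independent replicates with
fresh founders, sub-seeded from a master seed by a fixed splitting rule so
replicates are reproducible and order-independent, and reports the success
fraction with binomial standard error. Conditional summaries (trajectory
means, the adaptive-allele site frequency spectrum at a snapshot
generation) average only over establishing replicates.

Two companions: `viabilityCheck()` verifies that a source is
demographically viable at all under hard selection (100 founders must
double within 100 generations with probability above 0.95 at effectively
infinite $K$) — a conservative pre-check that establishment failures are
attributable to inbreeding or maladaptation rather than to an inviable
source. `branchingProcessPest()` approximates early establishment as
independent per-founder Poisson branching lines with mean
$m_k = e^{r_0} W_k$; the extinction probability per line is the smallest
root of $q = e^{m(q-1)}$ (fixed-point iteration from 0) and
$P_{est} = 1 - \prod_k q_k$. The approximation is expected to be accurate
exactly when founder growth is clearly positive and $K$ large, and the
test suite verifies this against the full simulation at 1000 replicates
(a scale at which the binomial error is ~1.5 percentage points).

# Experiment driver

`runExperiment()` executes a YAML-configured scan (architecture block,
source block, optional island block, one scan axis) and writes one TSV row
per grid point with all summaries plus provenance: a hash of the config, a
per-row sub-seed, and the package version, so any output row is
reconstructible from its embedded config and seed alone. Schema violations
(unknown keys, out-of-range selfing fractions, empty grids) are rejected
with the offending keys named; a grid point that fails at run time is
recorded with a failure marker without aborting the scan. A thin Rscript
wrapper lives in `inst/scripts/run-experiment.R`; the package functions
are the primary interface.

# Choosing the additive establishment regime

In the additive-only establishment scenario the dependence of $P_{est}$ on
the selfing fraction is only expressed near a threshold island selection
strength: when $2 \tilde s_1 L_A \ll r_0$ founders establish regardless of
$r_s$, and when $2 \tilde s_1 L_A \gg r_0$ they fail regardless. The
nominal threshold — founder load $2 \tilde s_1 L_A (1 - p)$ comparable to
$r_0$ — overstates what the full simulator tolerates, because weakly
selected standing variation is eroded by drift during the first
generations after founding, so the effective threshold must be located on
the simulator itself. For the validation suite we place the scenario at
$2 \tilde s_1 L_A = r_0 = 1.1$ (with $L_A = 1000$, $\mu_A = 10^{-4}$,
$\tilde s_0 = 0.001$, $N_0 = 10$), the implementation's own knife edge,
where the decline of $P_{est}$ with $r_s$ is well resolved at 300
replicates.

# Design decisions worth recording

* **Allele coding.** "1" is the allele disfavored in the source at both
  locus types. On the island the additive "1" allele becomes favored;
  recessive "1" stays deleterious everywhere. This matches the reversal of
  directional selection between habitats and keeps a single genome
  encoding valid in both.
* **Mixed-type ID normalizer.** The ID formula is defined for pairs of
  identical loci; for additive-recessive pairs we normalize the
  between-cohort covariance by $p_A(1-p_A) p_R(1-p_R)$. Any comparison of
  the three pairwise IDs in the package uses this convention.
* **LD statistic.** The simulator reports the gametic correlation $r$
  computed on the $2N$ phased haplotypes (phase is known), not the
  composite genotypic statistic; under the studied parameters it is
  negligible, which the cohort model also predicts.
* **Mean-load identity.** The mixture mean of the load distribution equals
  $\sum_i f_i E[G \mid i]$ exactly and is tested as such;
  $-\sum_i f_i \ln \bar w_i$ agrees with it only to first order in $s$
  (Jensen gap of order $s^2$ per locus), so tests treat the log-fitness
  form as an $O(s)$ consistency check rather than an identity.
* **Initial simulator genotypes** are monomorphic favorable by default
  (overridable); equilibrium statistics do not depend on this, which is
  itself a tested property.
* **Success criterion timing.** Success is evaluated exactly at generation
  $T$, not as "threshold ever exceeded"; a population can overshoot and
  crash back, and the two definitions genuinely differ near criticality.

# Known limitations

* The cohort model is deterministic: no drift, so it describes large
  sources only, and it systematically underestimates purging where
  within-cohort associations matter most — nearly recessive alleles with
  high genomic mutation rates at low selfing fractions. The validation
  tolerances above are calibrated claims about this error at moderate
  interference; in the strong-interference corner ($U_R/hs$ of several
  hundred and above at low $r_s$) the model's inbreeding depression can
  exceed the simulated value by more than its tolerance, and founder sets
  sampled from it carry correspondingly too much masked load — which also
  floors low-selfing establishment probabilities in that corner.
* Conversely, at the reduced validation scale a simulated population of
  N = 2000 is small enough that drift depresses the mean frequency of
  nearly recessive alleles below any deterministic prediction ($N h s$ of
  order 1); a single-locus diffusion calculation reproduces the deficit,
  so disagreement in that cell measures the finite population, not the
  recursion.
* Selfing fractions very close to 1 (above ~0.95) are outside the model's
  remit: strongly reduced effective size and interference between
  weakly selected alleles make even large simulated populations deviate
  from any deterministic treatment.
* Two locus types with identical within-type effects; no linkage, no
  epistasis, no distribution of effect sizes, no mating-system evolution,
  no recurrent migration. These are modelling scope choices, not missing
  features of the implementation.

# A worked example

```{r example, eval = FALSE}
arch <- architectureParams(LA = 1000, LR = 5000, muA = 1e-4, muR = 1e-4,
                           s = 0.05, h = 0.02, s0Tilde = 0.005)
reg <- sourceRegime(arch)
eq <- ilecEquilibrium(arch, reg, rs = 0.5)
populationSummaries(eq, arch, reg)

isl <- islandParams(arch, rs = 0.5, s1Tilde = 5e-4, r0 = 1.1, K = 1000,
                    N0 = 10)
estimateEstablishmentProbability(eq, arch, isl, R = 500, seed = 1)
```

The README shows a smaller example with the numbers it prints.
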