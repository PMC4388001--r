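---
title: "Methods: BLUP selection under four measures of coancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BLUP selection under four measures of coancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coansel)
```

## The question

Truncation selection on BLUP estimated breeding values (EBVs) maximizes
short-term genetic gain, but it also accumulates coancestry and inbreeding,
eroding the genetic diversity that future selection depends on. The EBVs can
be driven by different relationship matrices: the classical pedigree-based
additive relationship, or genomic relationships computed from dense marker
panels. `coansel` simulates closed breeding populations under truncation
selection with any of four relationship matrices and tracks, every
generation, the genetic gain *and* all four coancestry measures, inbreeding
and observed heterozygosity — whichever matrix drives selection. This
cross-performance design lets one ask, e.g., how selecting on the pedigree
matrix changes molecular coancestry, and vice versa.

## The simulation model

### Neutral base population

A diploid population of $2N_b$ individuals (half males, half females)
carries a genome of $c$ chromosomes, each 1 Morgan long with $L_c$ equally
spaced biallelic loci. Alleles are initialized uniformly at random (initial
heterozygosity 0.5) and the population evolves under non-overlapping random
mating: each generation every allele copy mutates (flips $0 \leftrightarrow
1$) with probability $\mu$, then each offspring draws a sire and a dam
uniformly with replacement; each parent transmits one gamete formed with a
$\text{Poisson}(\text{1 Morgan})$ number of crossovers at uniform positions
(Haldane model, no interference), with the starting strand chosen at random.
The burn-in runs the population towards mutation–drift equilibrium; the
returned `het_history` lets the user inspect the trajectory rather than
trusting a fixed stopping rule.

Defaults at full scale are $N_b = 500$ pairs (1000 individuals), 10
chromosomes of 10,100 loci and $\mu = 2.5\times10^{-3}$ per position and
generation. Because a 10,000-generation, 101,000-locus burn-in is far beyond
an interactive R session, the package's working scale — used throughout the
tests and examples — is 2 chromosomes of 500–1000 loci, $N_b = 50$ pairs and
a burn-in of 200 generations, which reaches its (lower, because $N_e$ is
smaller) heterozygosity plateau comfortably.

Mutation order: during the burn-in, parents are mutated first and then bred.
In the recorded phases below, mutation is instead applied to the newly
formed offspring gametes, so that an individual's genotype is immutable from
birth — once it has been phenotyped and used in a relationship matrix it
never changes. The per-copy, per-generation marginal mutation rate is
identical under both conventions.

### Replicates, trait and phenotypes

Each replicate draws from the shared base population: $n_S$ QTL positions
sampled uniformly among loci with allele frequency strictly inside
$(0.05, 0.95)$, and $N$ founder sires plus $N$ founder dams sampled without
replacement. True breeding values are

$$\mathrm{TBV}_i = \sum_{j=1}^{n_S} a_j\,(x_{ij} - 1), \qquad
a_j \sim \mathcal N(0, 1),$$

with $x_{ij}$ the count of allele 1 at QTL $j$. The additive variance
$\sigma^2_a$ is the empirical variance of the TBVs over the whole base
population, and $\sigma^2_e = \sigma^2_a (1 - h^2)/h^2$ fixes the
heritability. Phenotypes are $y_i = \mu + \mathrm{TBV}_i + e_i$ with $\mu =
100$ (it cancels from all EBV comparisons) and $e_i \sim \mathcal N(0,
\sigma^2_e)$, one record per individual, assigned at birth.

Six generations of random mating among the $N + N$ current parents are
recorded in the pedigree before selection starts; this gives the pedigree
matrix a history to work with, as molecular markers implicitly carry the
whole population history while genealogies usually begin with the programme.

### The four relationship matrices

All matrices are stored as relationships $= 2f$, twice the coancestry, the
scale on which the pedigree matrix has diagonal $1 + F_i$:

* **A** (genealogical): tabular recursion, $a_{ii} = 1 + a_{sd}/2$ and
  $a_{ij} = (a_{js} + a_{jd})/2$; founders unrelated and non-inbred.
* **G** (identity by state): per marker, the fraction of the four ordered
  gamete pairs between two individuals carrying identical alleles, averaged
  over the $M$ panel markers,
  $f_G(i,k) = \tfrac{1}{4M}\sum_n \sum_{l,m} I_n(l_i, m_k)$.
  The self terms use the individual's own four gamete pairs, so
  $f_G(i,i) = 1 - H_i/2$ with $H_i$ the observed heterozygosity.
* **R** (shared segments / ROH): for each ordered gamete pair, maximal runs
  of contiguous identical markers are collected; runs of at least
  `min_run` markers (default 100, held constant across panel densities, as
  a shared segment between parents is a potential run of homozygosity in
  the offspring) contribute their length, and
  $f_R(i,k) = \tfrac{1}{4L}\sum_j \sum_{a,b} L_j(a_i, b_k)$.
  Both run lengths and $L$ are measured in marker counts, so numerator and
  denominator stay in identical units at every density; runs never span
  chromosome boundaries.
* **V** (frequency-corrected): $f_V(i,k) = \tfrac{1}{M}\sum_n
  (g_{in}-p)(g_{kn}-p)/(p(1-p))$ with gene frequency $g = x/2 \in
  \{0, \tfrac12, 1\}$ and all reference frequencies fixed at $p = 0.5$.
  (Coding $g$ from allele 0 instead only flips a sign inside the symmetric
  product and leaves $f_V$ unchanged.)

Inbreeding is reported with the uniform rule $F_i = K_{ii} - 1$ on the
relationship scale, which reduces to the pedigree inbreeding coefficient
for A, the observed homozygosity excess for G (a fully heterozygous
individual has $F = 0$), the own-gamete ROH fraction for R, and the
frequency-centered homozygosity excess (possibly negative) for V.

**A useful identity.** With $p$ fixed at $\tfrac12$ the IBS and
frequency-corrected matrices are affine images of one another:
per marker the four-gamete match count equals $2(x_i-1)(x_k-1) + 2$, so
$K_G = \mathbf{J} + K_V/2$. Since the all-ones matrix $\mathbf{J}$ is
absorbed by the fitted mean and the scale factor is absorbed by the REML
variance, BLUP selection on G and on V is the *same* selection rule: under
matched seeds the package produces bit-identical G-driven and V-driven
trajectories. This explains why the two measures are empirically "hardly
distinguishable" in this design, and it is exploited as a consistency check
in the test suite.

### Variance components: Monte-Carlo EM REML

Each selection generation the additive and residual variances are
re-estimated under the model $y = \mathbf 1\mu + u + e$, $u \sim \mathcal
N(0, K\sigma^2_a)$, by a stochastic (Monte-Carlo) EM algorithm: one Gibbs
sweep per EM iteration draws $(u, \mu)$ from their full conditionals given
the current variances, then the M-step updates $\sigma^2_a \leftarrow u'
K^{-1} u / q$ and $\sigma^2_e \leftarrow e'e/n$; the estimates are the
means of the post-burn-in iterates (default schedule 6000 iterations with
1000 discarded; the test suite uses a 600/100 fast schedule).

The E-step is implemented in the eigenbasis of $K$, computed once per call:
the full conditional of the rotated effects is diagonal there, so each sweep
is an *exact joint* draw costing one $O(n^2)$ back-rotation, and no matrix
is ever re-factorized inside the chain — the motivation for Monte-Carlo EM
over exact REML schemes, which refactorize at every step. A variance floor
of $10^{-8}$ prevents the chain from being absorbed at zero, and eigenvalues
are floored at $10^{-10}$ so positive semidefinite and mildly indefinite
matrices are handled uniformly. The reported Monte-Carlo standard errors
are naive (no autocorrelation correction) and should be read as lower
bounds. A `use_true_variances` switch bypasses REML and plugs in the
calibrated simulation variances, supporting the alternative reading in
which variance components are treated as known.

### BLUP and truncation selection

EBVs solve Henderson's mixed-model equations with a single overall mean
($X = \mathbf 1$) and one record per individual ($Z = I$):

$$\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1} \end{pmatrix}
\begin{pmatrix} \hat\mu \\ \widehat{\mathrm{EBV}} \end{pmatrix} =
\begin{pmatrix} X'y \\ Z'y \end{pmatrix}, \qquad
\lambda = \sigma^2_e / \sigma^2_a,$$

solved exactly by a dense factorization (populations stay in the low
thousands). All individuals from the founders through the current cohort
enter with their own record; the current cohort's EBV components rank the
candidates. Within each sex independently the top 50% are kept (ties broken
towards the lower id, for determinism) and the selected sires and dams are
mated at random with replacement to produce $N$ male and $N$ female
offspring. Selection runs for 15 generations at full scale.

Numerical safeguards: G, R and V receive a $10^{-6}$ diagonal ridge before
inversion (they are near-singular over close relatives); A is ridged only
if its factorization fails. The segment-based matrix R is *not* guaranteed
positive semidefinite — thresholding runs breaks the Gram structure — so
when even the ridged Cholesky fails, the inverse is taken on the
eigenvalue-floored (nearest-PSD) matrix.

### Metrics and scaling

Per generation and per cohort (the current $2N$ candidates) the package
records mean TBV, the mean pairwise (off-diagonal) coancestry under all four
matrices, the mean inbreeding per matrix kind, and observed heterozygosity.
Gains are reported as differences from the last pre-selection cohort, and
coancestry trajectories on the log scale $\log[(1-f)/(1-f_0)]$ with $f_0$
the same pre-selection baseline, so the fastest decay marks the fastest
diversity loss. On generation indexing: with 6 recorded random-mating
generations and selection "from generation 7 onwards", the first selection
event necessarily acts on the generation-6 cohort; the baseline is
therefore the generation-6 value — the quantity the study's figure captions
call $f_7$, "right before selection started".

## Choices made where the design was open

* **QTL count at working scale.** The full-scale design uses 1000 QTLs
  among 101,000 loci (~1%). On a 2 × 1000-locus genome we use 200 QTLs
  (10%): a smaller count would not be meaningfully polygenic, while the
  full 1000 would make half the panel causal. Chosen once, before any
  experiment was run.
* **Founder and QTL draws** are independent across replicates (replicate
  $r$ seeds the generator with `seed + r`); all replicates share one base
  population.
* **QTLs stay inside the marker panel** at full density (where the panel is
  every position); thinned panels drop loci by stride regardless of QTL
  status.
* **Mutation continues** during the recorded and selection phases at the
  same rate, keeping the genetic model uniform end to end.
* **All phenotyped generations stay in the MME**; no forgetting of old
  records (a cap would be a trivial extension).
* **Offspring sexes** are assigned deterministically (first $N$ male), which
  is distributionally equivalent to random assignment here because parents
  are drawn independently per offspring.

## What the generator does and does not emulate

The generator reproduces the mechanisms the study design depends on —
drift, symmetric per-site mutation, Haldane recombination on a mapped
genome, random union of gametes, pedigree accumulation, a strictly additive
polygenic trait — and the working scale reproduces the qualitative
machinery results: selection response, coancestry accumulation, and the
*genealogical* side of the diversity question (pedigree coancestry grows
fastest when the pedigree matrix itself drives selection). It does not
emulate: sequence-context mutation or allele ages, variable chromosome
sizes or recombination hotspots, dominance/epistasis, or overlapping
generations.

Scale matters for two headline patterns, and passing tests at working scale
demonstrate mechanisms, not full-scale effect sizes:

* *Histogram variances.* In full-scale conditions the genealogical
  coancestry histogram has the largest variance of the four. At desk scale
  (hundreds to a couple thousand markers) the marker-sampling and LD noise
  in $f_R$ and $f_V$ inflates their spread above A's, so the tests assert
  only the scale-robust part of that ranking (G tightest; A and R wider
  than G).
* *Molecular diversity loss.* In full-scale conditions pedigree-driven
  BLUP loses the most marker diversity at similar gain. On a 2-chromosome
  genome drawn from a small base population, LD blocks are so large that
  the more accurate genomic BLUP realizes substantially more gain than
  shallow-pedigree BLUP and drags marker diversity down with its sweeps:
  the per-unit-of-gain diversity cost of the modes is equal at this scale,
  so the $f_G$ ordering follows the gain ordering rather than the
  full-scale pattern. Fragmenting the same marker count over 10
  chromosomes nearly equalizes the modes. The corresponding acceptance
  check is kept at its full-strength thresholds and documents this as a
  genuine reduced-scale limitation.

One exact identity is worth knowing when interpreting comparisons: the
dioecious mating scheme (no selfing) delays inbreeding by one generation
relative to the textbook monoecious Wright-Fisher model, so neutral
heterozygosity decays as the two-sex recursion predicts, not exactly as
$(1 - 1/(2N))^t$; the drift test derives and uses the exact form.

## Problem sizes used by the tests

The test suite runs everything at working scale: bases of 40–100
individuals on 2-chromosome genomes of 50–1000 loci per chromosome, REML
chains of 200–800 iterations, and the comparative selection experiment at
$N = 10$, $h^2 = 0.25$, 2 × 1000 markers, 10 selection generations and 30
replicates per selection mode. These sizes were chosen so that the complete
suite exercises every pipeline stage, including the four-mode comparison,
in minutes on a single core while keeping the Monte-Carlo error small
enough for the stated tolerances.

## Known limitations

* Exact REML (AI-REML) is deliberately not implemented; the Monte-Carlo EM
  estimates carry sampling noise that shrinks with chain length.
* The ROH measure uses exact allele-match runs (no genotyping error
  tolerance, no probabilistic HMM calling) and marker-count length units.
* VanRaden's matrix uses the fixed reference frequency $p = 0.5$; the
  observed-frequency variant is out of scope.
* No optimum-contribution selection or mate-allocation strategies; plain
  truncation selection only.
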