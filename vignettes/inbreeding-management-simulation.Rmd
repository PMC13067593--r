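---
title: "Comparing relationship matrices for IBD-based inbreeding management"
author: "ocsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing relationship matrices for IBD-based inbreeding management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocsim)
```

## The question the package addresses

Optimum contribution selection (OCS) maximizes the genetic merit of the
contributions of selection candidates, $c'\hat{g}$, subject to a bound on the
group coancestry $c'Ac/2$, non-negative contributions, and each sex
contributing half the genes of the next generation.  The quality of the
inbreeding management depends entirely on the relationship matrix $A$ used in
the constraint.  `ocsim` simulates a breeding population forward in time with
*traceable descent* — every founder gamete carries a unique allele code that
is co-inherited with the actual alleles — so that the true identity-by-descent
(IBD) relationship matrix is known exactly, and competing genomic estimators
of it can be compared both as *estimators* (regression, concordance, rate of
inbreeding) and as *management tools* (what happens when the OCS constraint
uses them).

The competing constructions are:

* **VanRaden method I** (`gVanRaden`), $G = (M-2P)(M-2P)'/2\sum_i p_i(1-p_i)$,
  centred either with the allele frequencies of the OCS base population
  (VR\_BF) or with the current generation's frequencies, recomputed every
  cycle (VR\_CF).
* **Runs of homozygosity** (`collectPopulationSegments` + `gRoh`), the de
  Cara-style segment matrix: the diagonal is $1+\sum_k L_{seg_k}(a_1,a_2)/L$
  and the off-diagonal averages the shared-segment length over the four
  gamete combinations of two individuals, $\left[\sum L(a_1,b_1) + \sum
  L(a_1,b_2) + \sum L(a_2,b_1) + \sum L(a_2,b_2)\right]/2L$.  Segments are
  maximal runs of identical alleles on phased haplotypes, kept when they
  span at least 20 SNPs and a minimum genetic length (1, 5, 8 or 10 cM).
* **Linkage analysis / FGLA** (`inferSegregationIndicators` + `gFgla`):
  segregation indicators — which parental haplotype each gamete copied at
  each SNP — are read off the phased data wherever the parent is
  heterozygous, imputed from the nearest informative locus on the same
  chromosome elsewhere, or drawn by a fair coin on chromosomes with no
  information; unique alleles given to the base animals are then
  gene-dropped through the pedigree along these indicators and relationships
  are averaged over loci.
* **True IBD** (`gTrueIbd`), computed from the simulator's founder allele
  codes: the benchmark all others are judged against, and itself usable as
  the OCS constraint.

## The simulation model

**Historic population.**  A neutral Wright–Fisher burn-in (`wfBurnIn`)
generates standing variation with realistic linkage disequilibrium: constant
population size, Haldane (Poisson) recombination on a uniform genetic map,
and infinite-alleles mutation at uniformly placed candidate sites, run from a
monomorphic start for $10\,n_e$ generations to approach mutation–drift
equilibrium (heterozygosity $\theta/(1+\theta)$ with $\theta = 4 n_e \mu$).
Polymorphic sites are recoded biallelic (most frequent allele versus the
rest).  A coalescent simulator could replace this stage; only the frequency
and LD structure of the panel matters downstream.

**Panels and trait.**  Three disjoint panels with minor allele frequency
above 1% are sampled: SNPs (used for estimation and management), neutral
monitoring loci (never used by the machinery), and QTL.  QTL effects are
drawn from a normal distribution and rescaled so the founder-era true
breeding values have unit variance; with $h^2 = 0.25$ the residual variance
is $(1-h^2)/h^2 = 3$.

**Base phase.**  Founders (100 males + 100 females by default) receive two
globally unique founder-allele codes each and mate at random for 10
generations, 400 offspring per generation, each generation breeding through
a pool of 100 sires and 100 dams so that inbreeding accrues at roughly
$1/(8N_m)+1/(8N_f) = 0.25\%$ per generation.  Meiosis is Poisson
recombination with a fair-coin starting haplotype per chromosome; the
founder-code track recombines with *identical* breakpoints, which is what
makes descent exactly traceable.  No mutation occurs after the burn-in.

**Selection phase.**  Ten cycles of: phenotype the newest cohort; GBLUP over
all animals born since the OCS base (EBVs from the mixed model
$\hat{u} = G(G+\lambda I)^{-1}(y-1\hat\mu)$, $\lambda = (1-h^2)/h^2$, with
the VR\_BF matrix — or the true IBD matrix in the `IBD_FULL` scheme); build
the scheme's constraint matrix among the candidates; bound the group
coancestry by $C_t = 1-(1-F_0)(1-\Delta F)^t$ with $\Delta F = 0.5\%$ and
$F_0$ the base population's mean coancestry *as measured by the scheme's own
matrix*; solve the OCS problem; and draw 400 matings with parent
probabilities proportional to the optimal contributions.

## Numerical choices

* **OCS solver.**  For a fixed active set the optimum decomposes as
  $c = u + x\,v$ where $u$ is the minimum-coancestry mix, $v$ the projected
  merit direction (the cross term $u'Av$ vanishes), and a binding constraint
  gives $x = \sqrt{(2C-u'Au)/v'Av}$ in closed form; negative contributions
  are eliminated iteratively (keeping at least the best candidate per sex)
  exactly as in the classical iterative OCS algorithm.  The
  unconstrained-merit (truncation) solution is returned when it already
  satisfies the bound; an unattainably low bound returns the
  minimum-coancestry mix flagged `feasible = FALSE`.  Solutions on small
  instances match a fine-grid search over both sex simplices.
* **Segment conventions.**  Segment endpoints are the map positions of the
  first and last SNP of a run, treated as half-open `[start, end)` cM
  intervals; both the 20-SNP and the minimum-length filters apply to maximal
  runs before merging; a single scan already yields disjoint runs, and
  `mergeOverlapping` guards inputs assembled from external segment files.
  On error-free phased data identity-by-state runs proxy IBD, accepting that
  the filters remove most chance runs.
* **Imputation ties.**  A locus equidistant from two informative loci copies
  the one at the smaller position; a chromosome with no informative locus
  receives one fair coin for all its loci.
* **Regularization.**  Where a factorization reports
  non-positive-definiteness (possible for near-singular genomic matrices), a
  `1e-6` diagonal ridge is added and escalated; GBLUP itself never inverts
  $G$, it factorizes $G + \lambda I$.
* **Denominators.**  Sample ($n-1$) variances and covariances are used for
  $\sigma_u^2 = var(TBV)$, regression and concordance; the mean coancestry
  of a cohort for rate-of-inbreeding estimation is the mean off-diagonal
  relationship over unordered pairs divided by two.
* **Heterozygosity.**  $Het_0 = 2q_0(1-q_0)$ by definition;
  $Het_t$ is the observed heterozygote frequency.  Diagnostics in the random
  phase are referenced to the founders and in the selection phase to the OCS
  base, matching the definition of generation 0 as the population in which
  OCS starts.

## Diagnostics

Per generation the pipeline reports the mean true IBD inbreeding (diagonal
of $G_{IBD}$ minus one), drift-based inbreeding
$F_{drift,i} = 2(q_{t,i}-q_{0,i})^2/Het_{0,i}$ and homozygosity-based
inbreeding $F_{hom,i} = (Het_{0,i}-Het_{t,i})/Het_{0,i}$ (averaged over
loci, separately for neutral loci and SNPs), the genic variance
$\sigma_a^2 = 2\sum_i p_i q_i a_i^2$, $var(TBV)$, mean true and estimated
breeding values, the number of parents selected (contributions above
$10^{-9}$), and QTL alleles fixed or lost.  Under pure random mating
$F_{drift} \approx F_{hom} \approx F_{IBD}$; a divergence under management
means the scheme systematically moves allele frequencies — the sign of
$F_{drift}-F_{hom}$ is proportional to the covariance between initial
frequency and frequency change.  Rates of inbreeding are the OLS slope of
$-\log(1-f_t)$ on generation, which recovers $-\log(1-\Delta f) \approx
\Delta f$ exactly for geometric series.  Agreement between an estimated and
the true matrix is summarized by regressing the estimate on the truth
(intercept, slope, SE) together with Pearson correlation and Lin's
concordance correlation coefficient
$2\,cov(x,y)/(var(x)+var(y)+(\bar x-\bar y)^2)$, separately for diagonals
(inbreeding) and off-diagonals (coancestry).

## Scale, defaults, and what the tests show

The package defaults are a desk-scale study: 3 chromosomes of 100 cM,
15,000 burn-in sites with per-site mutation rate $2.5\times10^{-4}$ and
$n_e = 200$ (chosen so the sampled panels of 3,000 SNPs / 1,000 neutral loci
/ 500 QTL at MAF > 1% are comfortably available), 200 founders, 400
offspring per generation, 10 + 10 generations.  One replicate runs in about
a minute on a laptop core; the acceptance script uses 8 replicates.  The
full-scale design (30 chromosomes, 3 Gbp, $n_e = 1000$, 50,000 SNPs, 50
replicates) is reachable through the same configuration interface but is not
what the test suite exercises.

The generator reproduces the *mechanisms* — LD from a finite historic
population, traceable descent, Bulmer-type variance loss under selection,
drift versus homozygosity divergence under non-IBD constraint matrices —
but not every feature of real data: there is no genotyping or phasing
error, no mutation during breeding, no overlapping generations, discrete
generations with a fair sex ratio, and the genetic map is uniform (1 cM per
Mb when exporting physical coordinates).  Passing tests therefore validate
the algorithms and their interplay under idealized conditions, not the
field performance of any matrix on noisy data.

Monte-Carlo checks in the test suite compare against independent oracles:
the neutral-equilibrium heterozygosity for the burn-in; the kinship
recurrence $\theta_{t+1} = \theta_t + c(\alpha_t-\theta_t)$,
$c = 1/(4N_m)+1/(4N_f)$, for the random-mating phase; junction theory
(mean shared-segment length $1/(2t)$ Morgan for an ancestor $t$
generations back, sampled by an interval-arithmetic gene-drop that bridges
uninformative gaps with the Haldane flip probability
$(1-e^{-2d})/2$); naive run-scans for segment detection; the tabular
pedigree relationship matrix for the expectation of the FGLA gene-drop;
and grid searches for the OCS optimum.

## Design choices that were genuinely open

* The interpretation of the true-IBD off-diagonal ("across all possible
  gamete combinations, divided by twice the number of loci") is taken as
  the gametic-matrix average, $\tfrac12\sum_{4\ \mathrm{combos}}$ (identity
  fraction), which reproduces 0.5 for parent–offspring with unrelated
  non-inbred parents and 2 for clones of a fully inbred line.
* Founders are distinct haplotype pairs drawn without replacement from the
  historic panel.
* The FGLA base defaults to the OCS base generation (the matrix can only
  see inbreeding accumulated after its base); for whole-series
  rate-of-inbreeding comparisons it is anchored at the founders, as are the
  VR\_BF reference frequencies, via configuration.
* Candidates are the full current generation, and all animals born since
  the base contribute phenotypes to GBLUP, symmetrically across schemes.
* Each offspring draws its sire and dam independently (with replacement)
  proportional to contributions; matings are not deduplicated.
* Matrix-agreement tables can pool all generations or use only the final
  one (`generations` argument); both are provided because either reading of
  a cross-generation comparison is defensible.

## Known limitations

`IBD_FULL` (true-IBD GBLUP) recomputes the full cumulative IBD matrix each
cycle and is quadratic in the number of phenotyped animals; it is intended
for reduced-scale experiments.  The FGLA scheme materializes the full
pedigree-genotype history each cycle for the indicator inference.  The OCS
solver's elimination heuristic does not allow re-entry of eliminated
candidates; in the regimes tested the solutions match the grid oracle, but
adversarial matrices could in principle require a full active-set method.
Segment detection is exact IBS on error-free phase; it is not a
phasing-error-tolerant model.

## A minimal run

```{r example, eval = FALSE}
cfg <- schemeConfig(scheme = "IBD", dF = 0.005, nSelectGenerations = 10,
                    seed = 1)
res <- runScheme(cfg)
schemeReport(res)          # per-generation diagnostics
deltaFSlope(schemeReport(res)$meanFIbd)$slope   # realized rate
```
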