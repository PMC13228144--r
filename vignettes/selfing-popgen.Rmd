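---
title: "Selfing rates, ancestry and admixture recency from unlinked SNPs"
author: "selfpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selfing rates, ancestry and admixture recency from unlinked SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfpop)
```

## The problem

Predominantly selfing plants - including many invasive colonizers - leave a
characteristic genomic signature: very low observed heterozygosity within
populations, strong differentiation among them, and, when lineages
occasionally outcross, admixed individuals whose heterozygosity decays
again over subsequent selfing generations. `selfpop` packages the
computational core of such an analysis for unlinked biallelic SNP data:
estimating per-population selfing rates from multilocus identity
disequilibrium, simulating partially selfing lineages, inferring ancestry
with a maximum-likelihood admixture model, dating the recency of admixture
by comparison with simulated hybrid classes, screening for clones with
KING-robust kinship, and exporting folded site-frequency spectra and
divergence-time conversions for downstream demographic work.

All analyses consume one container, the `genotype_matrix`: individuals by
loci, genotypes coded 0/1/2 (count of the alternate allele), `NA` for
missing, with sample, population and locus metadata. Statistics are
complete-case per locus or per pair; nothing is imputed except in PCA,
where mean imputation is the explicit, documented method.

## The mixed-mating model

The model underlying both the simulator and the estimator is mixed mating
at equilibrium. Each generation an offspring is produced by selfing with
probability $s$ and by random outcrossing otherwise. An individual's
number of consecutive selfing ancestor generations $G$ is then geometric,

$$P(G = g) = (1 - s)\, s^g .$$

Conditional on $G$, each locus is heterozygous with probability
$2 p q\, (1/2)^G$: every selfing generation halves heterozygosity. Two
standard equilibrium identities follow:

* the inbreeding coefficient $F_{IS} = s / (2 - s)$, so
  $H_O = H_E (1 - F_{IS})$;
* the identity disequilibrium
  $g_2 = \dfrac{E[x^2]}{E[x]^2} - 1 = \dfrac{s}{(1 - s)(4 - s)}$ with
  $x = (1/2)^G$.

The second identity is the basis of the multilocus estimator: because $G$
is shared by all loci of an individual, heterozygosity is *correlated
across loci within individuals*. That correlation (identity
disequilibrium) separates real variance in inbreeding from a mere
heterozygote deficit, and is robust to null alleles and scoring artefacts
that depress heterozygosity locus by locus.

`simulate_mixed_mating_population()` draws $G$ once per individual
(shared across loci - this is what generates $g_2 > 0$) and then, per
locus, one allele from the population frequency and the second either
identical by descent (probability $1 - (1/2)^G$) or independent. The test
suite contains a deliberately mis-specified control in which $G$ is
redrawn per locus: it produces the same $F_{IS}$ but $g_2 \approx 0$,
confirming that the estimator reads the correlation, not the deficit.
$G$ is capped at 50 generations ($2^{-50}$ residual heterozygosity is
numerically zero), which also makes $s = 1$ safe (with a warning).

## The g2 estimator

With heterozygosity indicators $h_{il}$, row sums $r_i$, column sums
$c_l$ and total $T$,

$$\hat g_2 = \frac{\tfrac1n \sum_i (r_i^2 - r_i)}
  {\tfrac{1}{n(n-1)}\left(T^2 - \sum_i r_i^2 - \sum_l c_l^2 + T\right)}
  - 1,$$

the ratio of observed within-individual cross-locus co-heterozygosity to
its between-individual expectation. The closed form is checked against a
brute-force quadruple-sum oracle in the tests (exact equality).
`g2_to_selfing()` inverts $g_2 = s/((1-s)(4-s))$ through the quadratic
root in $[0,1)$; the round trip is exact to $10^{-10}$. Negative
$\hat g_2$ (sampling noise under little or no selfing) maps to
$\hat s = 0$ with a flag rather than an error, mirroring how
non-significant populations are reported in practice.

`estimate_selfing()` adds three layers around the point estimate:

* **Locus handling.** Loci with more than 20% missingness within the
  group are dropped, then at most `max_loci` (default 1000) are
  subsampled with the supplied seed - the common practice of estimating
  from a fixed SNP panel, and a bound on the permutation cost. Remaining
  missing cells contribute $h_{il} = 0$ to the sums; with missingness at
  the few-percent level this deflates numerator and denominator nearly
  proportionally. The full missing-data reweighting of the original
  RMES-style estimator is intentionally not reimplemented.
* **Permutation test.** The null of no identity disequilibrium is built
  by permuting each locus's heterozygosity column independently across
  individuals, which destroys cross-locus association while preserving
  per-locus heterozygote counts. The p-value uses the add-one convention
  $(1 + \text{exceedances})/(1 + n_\text{perm})$ and is never zero.
  Default 10,000 permutations.
* **Uncertainty.** `sd_s` is a bootstrap SD of $\hat s$, resampling
  **individuals** by default. This is a deliberate design choice: the
  sampling variance of $\hat g_2$ is dominated by between-individual
  variance in realized selfing depth $G$ (a population of $n = 18$
  effectively contains 18 draws of $x = (1/2)^G$), so a bootstrap over
  loci tracks only the small between-locus component and understates the
  SD several-fold at field-study sample sizes. We verified this by
  simulation: at $s = 0.905$, $n = 18$, $L = 1000$, the
  replicate-to-replicate SD of $\hat s$ is about 0.035; the individual
  bootstrap gives about 0.042 on average, while a locus bootstrap gives
  about 0.003. The locus bootstrap remains available via
  `boot_units = "loci"`.

Two honest limitations, quantified in the acceptance tests rather than
hidden: (i) at near-obligate selfing (e.g. $s = 0.985$, $n = 10$,
$L = 1000$) heterozygotes are so rare that in roughly half of simulated
replicates all of them sit in a single individual; the between-individual
denominator then vanishes and the estimate is *flagged undefined* - the
contract's degenerate outcome, not an error. Coverage statements are
therefore made over replicates with defined estimates. (ii) at small $n$
(9 individuals) the sampling distribution of $\hat s$ is heavy-tailed, and
a plus/minus two bootstrap-SD interval covers the truth in roughly 85-93%
of replicates rather than 95%, even when the SD itself is estimated
accurately (we verified with a model-based parametric bootstrap, which
gives the same shortfall). The interval is reported as a dispersion
summary, not an exact confidence procedure.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults describe the
study design it emulates: a two-range invasion survey of a predominantly
selfing plant.

* **Lineages.** Allele frequencies follow the Balding-Nichols model: an
  ancestral frequency $p_0 \sim U(0.05, 0.95)$ per locus (keeping loci
  informative, like SNP-discovery panels), then per lineage
  $p_k \sim \mathrm{Beta}(p_0(1-F_k)/F_k,\ (1-p_0)(1-F_k)/F_k)$ with an
  $F_{ST}$-like divergence parameter per lineage, star-shaped by
  default. Frequencies are clipped to $[10^{-6}, 1 - 10^{-6}]$. The
  `paper_like` preset uses $F$ between 0.20 and 0.35, native lineages
  more diverged than invasive ones - enough separation that clustering
  is unambiguous at genome scale, as observed in strongly structured
  selfers.
* **Populations.** 30 populations (26 invasive in three lineages, 4
  native, one of them fully outcrossing with correspondingly elevated
  diversity), sizes 1-18 individuals, per-population selfing rates
  spanning 0.23-0.99, about 6,000 unlinked loci.
* **Missingness.** Per-individual missing rates are Beta-distributed
  with mean 6.5% and concentration 4.25; the concentration was chosen by
  solving for the value whose median is 1.6%, reproducing the strongly
  right-skewed per-individual missingness profile of
  reduced-representation sequencing (a few poor libraries, most
  near-complete).
* **Planted admixture.** One invasive population is composed of
  inter-lineage hybrids: six historical F1s aged by 4-8 selfing
  generations, one recent backcross and two recent F1s; the native
  outcrossing population additionally hosts two recent F1s with an
  invasive lineage. The counts are fixed and configurable - no
  quantitative admixture rate is implied, only the presence of both
  recent and historical events. A `TruthRecord` (lineage, selfing depth
  $G$, hybrid class, post-admixture selfing generations) accompanies
  every simulated data set, enabling recovery tests.

What the generator does **not** emulate - and what passing tests
therefore do not establish about real data: realistic site-frequency
spectra (real SNP panels are skewed toward rare alleles; we use a flat
ancestral law), linkage, null alleles and allelic dropout, genotyping
error, spatial structure within populations, and clonal replicates. The
kinship screen, for example, is exercised on duplicated genotypes rather
than on a model of vegetative propagation.

## Ancestry inference

`admixture_em()` fits the standard admixture likelihood
$\sum_{il} [\,g_{il}\log f_{il} + (2-g_{il})\log(1-f_{il})\,]$,
$f_{il} = \sum_k q_{ik} p_{kl}$, by EM - the deterministic
maximum-likelihood counterpart of Bayesian MCMC clustering, with the same
likelihood family and outputs ($Q$, per-cluster allele frequencies,
log-likelihood). Initialization draws $Q$ rows from a symmetric
Dirichlet(1) and $P$ from $U(0.05, 0.95)$; the best of `n_restarts`
(default 10) final log-likelihoods wins, ties broken by restart index.
Missing genotypes are skipped with per-individual normalization by called
loci. Frequencies are clipped to $[10^{-6}, 1-10^{-6}]$; the
log-likelihood trace is retained and checked non-decreasing in the tests.
Convergence is declared when the increment falls below `tol` (default
$10^{-6}$); non-convergence returns the best iterate with a flag.

Model-choice summaries follow common practice: `evanno_delta_k()`
computes $\Delta K$ from replicate log-likelihoods (defined only for
interior $K$ with positive replicate SD), and the pipeline reports the
full table alongside the likelihoods - it never auto-selects a single
$K$, since the two criteria are well known to disagree on hierarchically
structured data. `admixture_degree()` summarizes each $Q$ row by its
population SD (divisor $K$; the sample-SD variant would only rescale by
$\sqrt{K/(K-1)}$). `pca_mean_impute()` mean-imputes missing genotypes per
locus, centers but does not scale columns (scaling would up-weight rare
alleles; the choice is documented and deliberate), and is deterministic
up to component sign.

`supervised_ancestry()` estimates a single admixture coefficient $q$
against two fixed parental frequency panels by bounded 1-D likelihood
optimization (tolerance $10^{-8}$), checked against a $10^{-4}$-grid
oracle in the tests.

## Hybrid classes and recency of admixture

`simulate_hybrid_classes()` builds hybrids genealogically per locus from
two parental pools: F1 (one allele from each pool), F2 (gametes of two
independent F1s), first-generation backcrosses (F1 gamete plus pool
allele) and second-generation backcrosses (gamete of a simulated
first-generation backcross plus pool allele). Eight class labels are
implemented (F1, F2, F1xA, F1xB, F1AxA, F1AxB, F1BxB, F1BxA), with a
subset option; descriptions of this design sometimes count six classes
by pooling the reciprocal second-generation backcrosses, so both usages
are served. Expected ancestry fractions halve with each backcross
(0.5, 0.75, 0.875, ...); with pools fixed for alternate alleles F1
heterozygosity is exactly 1 and F2, first- and second-generation
backcrosses have expectation 0.5, 0.5 and 0.25 - all asserted in tests.
`selfing_decay()` ages any set by $g$ selfing generations: $q$ unchanged
in expectation, heterozygosity halved per generation.

`classify_recency()` operationalizes the visual envelope comparison of
empirical against simulated hybrids. For each empirical $(q, H_O)$ point
it pools all simulated individuals within an ancestry window
$|q_{sim} - q| \le w$, doubling $w$ from 0.05 until at least 20 matches
are found or $w$ reaches 0.5; the envelope is the 2.5-97.5 percentile
band of matched simulated $H_O$. A point at or above the lower edge is
`recent` (consistent with some fresh hybrid class of comparable
ancestry), below it `historical` (heterozygosity already eroded by
selfing), and `unresolved` if matches never accumulate - a value, not an
error. Window, band and match threshold are configurable; whether a
fixed window or nearest-class rule is "the" right operationalization is
genuinely open, and the adaptive window was chosen because it degrades
gracefully where simulated mass is sparse. Crucially, empirical and
simulated individuals get their $q$ from the *same* supervised estimator
and the *same* parental pools, so the classification is internally
consistent.

## Kinship, SFS, divergence time

`king_kinship()` implements the allele-frequency-free KING-robust
estimator $\phi = (N_{hetHet} - 2N_{oppHom})/(N_{het,i} + N_{het,j})$
over the loci called in both individuals. Duplicated genotypes give
$\phi = 0.5$ exactly (forced by the formula); pairs with no
heterozygotes are undefined, never silently zero. Because the estimator
assumes a shared gene pool, it is computed within populations by
default. `kinship_flags()` bins pairs at the standard cutoffs
($> 0.45$ duplicate/clone, $0.354$-$0.45$ first-degree,
$0.177$-$0.354$ close relative).

`folded_sfs()` counts minor alleles per locus over complete-case loci by
default; with `projection_n` set, each locus with enough called alleles
is projected down by the hypergeometric expectation (counts become
real-valued, mass is conserved - asserted as an invariant). The SFS is
exported in a single-line count format for multi-epoch demographic
tools; no demographic model is fitted here.

`divergence_time()` applies $\tau = 2\mu t$, i.e.
$t = \text{generation time} \times \tau / (2\mu)$, with defaults
$\mu = 7\times10^{-9}$ per site per generation and a one-year generation
time.

## The pipeline

`run_pipeline()` sequences the stages (filter, kinship screen,
diversity, per-population selfing, ancestry sweep with $\Delta K$,
lineage-level selfing at a 0.999 purity threshold - 0.99 available as a
config variant - parental pools, hybrid simulation, recency calls, SFS
per cluster) from a single YAML-serializable config with one seed;
reruns are byte-identical. Rank tests comparing diversity between groups
are ordinary `stats` routines applied to the diversity table and are not
reimplemented. Degenerate configurations (a K range too short for
$\Delta K$) skip the affected stage with a logged notice rather than
failing.

## Problem sizes in the shipped tests

The test suite exercises the estimators at the operating points that
matter - selfing-rate recovery at $(s, n)$ = (0.905, 18), (0.233, 9),
(0.985, 10) with 1000 loci and 100 replicates each; equilibrium checks
at $n = 200$, $L = 2000$; test size at $s = 0$ over 500 replicates with
1000 permutations; recency classification on five full study-preset
simulations - and smaller seeded fixtures elsewhere. These sizes are the
package's own trade-off between statistical resolution and a test suite
that runs in minutes on one core.

## Known limitations

* The g2 machinery handles missing data by complete-case zeroing after a
  20% per-locus filter, not by the original estimator's full reweighting.
* `sd_s` is a dispersion summary; at $n \lesssim 10$ a 2-SD interval
  under-covers (see above), and near-obligate selfing yields flagged
  undefined estimates in a substantial fraction of small samples.
* The admixture model assumes unlinked loci and independent individuals;
  no correlated-frequency prior, no cross-validation error, no residual
  diagnostics.
* The recency classifier inherits the parental pools' quality: with few
  pure individuals the pool frequencies are noisy and the envelope
  widens accordingly.
* Divergence-time conversion is a unit change, not an inference; SFS
  export stops deliberately short of demographic model fitting.
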