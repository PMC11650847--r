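---
title: "Monitoring selection and drift in pedigreed populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring selection and drift in pedigreed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, and the places where the design
was genuinely open and a choice had to be made.

## The monitoring problem

A closed breeding line under index selection accumulates inbreeding and
changes allele frequencies every year. Any individual SNP trajectory
confounds two forces: directional pressure from selection on linked or
pleiotropic variation, and drift, whose magnitude is set by the effective
population size. The package's chain makes that comparison explicit: it
estimates the drift scale from the pedigree itself, simulates the
pedigree-exact drift null by gene dropping, and asks (a) whether observed
changes exceed that null and (b) whether they are predictable from
single-SNP association results.

## Effective population size from pedigree inbreeding

For the genotyped cohort born in year $t$, the mean kinship is
$f_t = \tfrac12\,\overline{A_{ij}}$ over unordered pairs $i \ne j$, where
$\mathbf A$ is the numerator relationship matrix computed by the tabular
method over the ancestor closure of the cohort (provably identical to
using the full pedigree, and cheaper). Under a constant rate of
inbreeding, $1 - f_t$ decays geometrically, so OLS of
$\ln(1 - f_t)$ on calendar year gives a slope $\hat b$ and
$$\widehat{\Delta f}_{year} = 1 - e^{\hat b},\qquad
  \widehat{\Delta f}_L = L\,\widehat{\Delta f}_{year},\qquad
  \widehat{N_e} = \frac{1}{2\,\widehat{\Delta f}_L},$$
with $L$ the generation interval (mean parent age at offspring birth, in
years) converting a yearly rate into a per-generation rate.

Assumptions and conventions:

* Cohorts are birth-year groups of **genotyped** animals, per line;
  years with fewer than two members are dropped with a warning. A
  per-line flag is exposed because pooling lines into one kinship series
  is also defensible when the pedigree is shared; the package defaults to
  per-line series and reports line-specific $N_e$.
* The regression uses calendar year, not cohort index, so missing years
  do not distort the slope.
* If kinship is non-increasing ($\widehat{\Delta f}_L \le 0$), $N_e$ is
  reported as undefined with a flag rather than an error — a real
  outcome for short series.
* The display value rounds half-to-even; the unrounded estimate is kept.
* Founders are animals with both parents unknown. An animal with one
  unknown parent side behaves exactly as if it had a unique phantom
  founder on that side: the unknown side contributes zero relationship
  in $\mathbf A$ and draws a fresh founder allele in gene dropping. No
  phantom records are materialized.

## The gene-dropping drift null

One biallelic locus per replicate: founders receive two alleles drawn
independently with carrier probability equal to the grid MAF
(Hardy–Weinberg), and every non-founder inherits one uniformly chosen
allele from each parent, in topological order (compiled kernel). Cohort
frequencies are computed over the same genotyped cohorts, by the same
estimator, as for real data. Defaults follow the standard protocol:
MAF grid 0.01–0.50 in steps of 0.01 and 1000 replicates per value.

The envelope conditions on the **realized baseline-year cohort MAF** of
each replicate (folded to $\le 0.5$, right-closed bins of width 0.01),
not on the founder-assignment MAF: observed SNPs are selected and binned
by their baseline-year MAF, so the null must be conditioned identically,
otherwise within-bin drift is understated for bins fed by larger founder
MAFs. Replicates fixed in the baseline cohort are excluded (observed
SNPs are segregating at baseline by construction) and counted. Bins with
fewer than 30 replicates are merged with a neighbor and flagged. Per
(line, bin, horizon year) the |Δp| summaries are the mean, a
normal-approximation 95% CI of that mean across replicates, upper
quantiles (0.95, 0.99) and the maximum. The CI is across replicates; an
across-SNP-equivalents CI would be narrower and is not what the envelope
represents.

Two properties anchor the implementation and are enforced in the tests:
the martingale property (expected cohort frequency equals the founder
MAF at every horizon) and agreement of the replicate variance with the
Wright–Fisher form $p_0(1-p_0)\,[1-(1-\tfrac1{2N_e})^t]$ on
discrete-generation random-mating pedigrees, with $N_e$ estimated from
the same pedigree. One accounting subtlety: the founder Hardy–Weinberg
assignment is itself a binomial sampling round ($2N$ alleles from an
infinite pool), so the cohort born $g$ generations after the founders
sits at $t = g + 1$ in that formula.

Randomness: one root seed; each MAF grid value runs in its own derived
stream (a deterministic function of the root seed and the grid index),
so grid batches are order-independent and a grid subset reproduces the
full run's values for the shared entries. Replicates within one batch
are generated sequentially by one kernel call and are not individually
re-seedable; we judged per-replicate streams not worth the RNG machinery
in R.

## Genotype handling

Dosages are counted-allele counts in {0, 1, 2} (ALT for VCF; declared
counted allele for TSV/PLINK-raw). QC applies, in a fixed order: animal
missingness > 5% (strict), exact-duplicate genotypes (identical calls
*and* identical missing pattern; the smallest id is kept), opposing-
homozygote rate against any genotyped parent above 2% (the standard
surrogate for an unstated pedigree-conflict rule), marker missingness
> 5%, then monomorphic markers. The order is fixed because the source
protocol does not state one; animal filters run before marker filters so
a bad animal cannot kill a good marker. QC is idempotent.

Residual missingness is mean-imputed per marker (a real number, not
rounded). This deliberately replaces haplotype-based imputation: after
the ≤ 5% missingness QC the worst-case perturbation of a frequency is
< 0.025, and downstream analyses (GRM, scan, frequency tables) are
insensitive at that level, while a phasing dependency would dominate the
package's installation footprint. Frequencies are always computed over
non-missing calls only.

## The mixed-model scan

Per trait the model is
$\mathbf y = \mathbf X\mathbf b + \mathbf Z_1\mathbf u + \mathbf Z_2\mathbf a + \mathbf w_i v_i + \mathbf e$,
$\mathbf a \sim N(0, \mathbf G\sigma^2_A)$, with $\mathbf G$ the VanRaden
method-1 GRM: $\mathbf G = \mathbf Z\mathbf Z^\top / 2\sum_i p_i(1-p_i)$,
$\mathbf Z = \mathbf M - 2\mathbf P$. Centering frequencies default to
the analyzed animals (all years pooled), which makes the grand sum of
$\mathbf G$ exactly zero.

Variance components are estimated **once** per analysis set by REML and
held fixed across the scan; per-SNP REML would be both slower and a
different estimand. Two REML paths:

* *Animal-only models*: eigendecomposition of the (subset) GRM reduces
  the restricted likelihood to a one-dimensional profile in the variance
  ratio $\gamma = \sigma^2_A/\sigma^2_E$, optimized by Brent search on
  $\log\gamma \in [-20, 20]$ (tolerance $10^{-9}$, i.e. successive
  log-likelihoods agree well below $10^{-8}$). A ratio at the search
  boundary is flagged, not an error.
* *Extra i.i.d. random factors* (batch, litter, herd-year-season, …):
  direct maximization of the restricted log-likelihood over log
  variances (Cholesky evaluation of $\mathbf V$, L-BFGS-B, started from
  an equal split of the phenotypic variance). We chose direct
  maximization over average-information updates on the mixed-model
  equations: at the moderate record counts this package targets the
  $O(n^3)$ likelihood evaluation is not the bottleneck, and the
  quasi-Newton path needs no separate convergence safeguards.

The scan absorbs the fixed effects once:
$\hat v_i = \mathbf w_i^\top\mathbf P\mathbf y / \mathbf w_i^\top\mathbf P\mathbf w_i$,
$\mathrm{SE}^2 = 1/\mathbf w_i^\top\mathbf P\mathbf w_i$ with
$\mathbf P = \mathbf V^{-1} - \mathbf V^{-1}\mathbf X(\mathbf X^\top\mathbf V^{-1}\mathbf X)^{-1}\mathbf X^\top\mathbf V^{-1}$
— algebraically identical to refitting the full GLS per SNP, which the
test suite verifies against an explicit normal-equations oracle to
$10^{-8}$ relative. Markers with $\mathbf w^\top\mathbf P\mathbf w$ below
$10^{-10}$ of the average (collinear with the fixed effects, e.g.
monomorphic in the analysis set) get an NA sentinel and keep their row.
Wald p-values use the standard normal by default (the large-n reference;
a residual-df t option exists). $-\log_{10}p$ is computed on the log
scale so extreme peaks do not underflow. $\lambda_{GC}$ divides the
median $z^2$ by 0.454936; QQ plotting positions are $k/(n+1)$.

Bonferroni thresholds use the fixed-m convention (all scanned SNPs)
regardless of NA sentinels, matching the usual reporting; an adaptive-m
variant is a one-liner the user can apply to the returned table.

The SNP enters the model with its (mean-)imputed dosage — fractional
values are allowed — because the same matrix feeds the GRM and the
frequency tables; re-reading raw calls for the scan would let the three
disagree.

## Allele-frequency-change analytics

All |Δp| statistics are invariant to allele recoding; signed statistics
are equivariant, and between-line comparisons therefore require shared
counted-allele metadata and refuse to run without it. MAF strata are
right-closed (a marker at exactly 0.05 falls in the lowest stratum) with
the conventional edges 0.05/0.10/0.20/0.50, folded at the baseline year.
"Change from the current to the next year" is implemented literally as
birth-year cohort $t \to t+1$ even though one year is ~0.7 generations
at $L \approx 1.4$; the per-generation reading would rescale slopes but
not $R^2$. The change-on-GWAS regressions pair |Δp| with |effect| and
with $-\log_{10}p$ by default — significance is unsigned, so the
unsigned pairing is the only coherent default — with a signed-on-signed
flag. Between-line $R^2$ uses signed changes (directional agreement is
the question); zero-variance predictors are flagged degenerate rather
than returning 0/0. Trajectory plots track the allele that was minor at
baseline; at exactly 0.5 the counted allele is kept, and the lead SNP is
the most significant with ties broken by smaller position.

## What the simulator emulates, and what it does not

`simConfig()` defaults describe a closed maternal line: seven genotyped
birth-year cohorts (2015–2021) on top of two founder cohorts, 20 sires
and 100 dams selected per year from age classes 1 and 2 years in a
60/40 split (generation interval exactly 1.4 by construction), litters
of six, ~600 offspring per year of which 67% are genotyped, 3000
unlinked biallelic markers over 18 chromosomes with founder frequencies
uniform on (0.01, 0.5), and 100 pleiotropic QTL (a shared set with
optionally correlated effects) behind two traits of $h^2 = 0.3$ combined
into an equally weighted index. Phenotypes add a sex effect, a year
batch effect (5% of variance), a litter effect (5%) and i.i.d. residual.
Selection truncates on the **true** index (fast and deterministic);
an EBV-based mode was judged unnecessary for any property tested. The
`random_pairs` mating design (every offspring draws independent parents)
exists for drift validation, where multinomial offspring counts make the
census size the effective size; the default `litters` design is the
realistic breeding scheme.

Deliberately not emulated: linkage (markers are unlinked, so hitchhiking
on neutral markers is absent — frequency change beyond drift arises only
at QTL), mutation, genotyping error, a real genome map, and the two-chip
intersection logic of commercial data. Passing tests therefore
demonstrate the statistical machinery under the stated structure, not
robustness to LD or data-cleaning pathologies of real chips.

## Problem sizes and calibration choices in the tests

The suite exercises: drift variance on a 10-generation, census-100
random-mating pedigree (1000 replicates, founder MAF 0.3, every horizon
within 20% of the closed form — the Monte-Carlo + $\hat N_e$ error
budget); $N_e$ recovery within 20% of census for $N \in \{50, 100\}$
(median of 20 pedigrees); scan-vs-oracle agreement at 300 animals;
null-scan p-value uniformity (KS at $\alpha = 0.01$) across 100 seeded
runs of 500 animals × 200 null SNPs; and ≥90% power for a planted QTL
explaining 2% of phenotypic variance at n = 2000 against the Bonferroni
threshold for m = 1000.

One calibration choice deserves emphasis. In the power benchmark the
GRM is built leaving out the candidate's chromosome. With marker counts
small relative to n, a candidate SNP included in $\mathbf G$ has its own
signal partially absorbed by the polygenic term (proximal
contamination), a well-known effect that leave-one-chromosome-out
scanning exists to remove; at tens of thousands of markers the effect is
negligible, which is why the pipeline default — matching the protocol
the package mirrors — keeps all SNPs in $\mathbf G$. The benchmark
measures the scan's power where the estimator is used as intended at
desk scale.

Drift-only calibrations run two independent 2000-marker lines over three
cohorts (between-line $R^2$ and change-vs-significance $R^2$ both below
0.01 in ≥95% of 20 seeded runs), and the selection contrast compares
mean |Δp| over seven cohorts between index truncation and random
selection on eight paired seeds (one-sided paired t-test). The |Δp|-on-
|effect| regression is *not* part of that null battery: under drift both
|Δp| and the magnitude of an estimated null effect scale with
$\sqrt{p(1-p)}$ (the latter inversely), inducing a small negative
MAF-driven correlation that the significance-based regression does not
share; the MAF filter argument (`mafMin`) exists for exactly this
analysis.

## Known limitations

* The A-matrix is dense; pedigrees beyond ~20k ancestors of the cohorts
  of interest will be slow and memory-hungry. Sparse-inverse methods
  were out of scope.
* REML with extra random factors is $O(n^3)$ per likelihood evaluation;
  intended for the desk-scale designs above, not for 30k-record national
  evaluations.
* The gene-drop null conditions on the pedigree and cohort definitions;
  it does not model genotyping-set churn (animals genotyped on different
  chips across years).
* The index "heritability" of an EBV-like response column is treated as
  an ordinary variance ratio by the REML machinery; interpret
  accordingly.
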