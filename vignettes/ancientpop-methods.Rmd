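---
title: "Methods: population-structure analyses for ancient DNA cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-structure analyses for ancient DNA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancientpop)
```

## Scope

`ancientpop` implements the statistical core of a population-structure
study of a low-coverage ancient-DNA cohort: f3/f4 statistics with block
jackknife errors and a cladality screen, qpAdm-style admixture modelling
with a distal model search, PCA with least-squares projection of sparse
pseudo-haploid genomes, a geographically matched resampling test for
ancestry heterogeneity, READ-style kinship, read-fraction genetic sexing
and chrY haplogroup scoring. A synthetic-data module generates every
input with known truth, and the package ships the metadata table of a
91-individual North Pontic cohort (sites, archaeological group labels,
calibrated or archaeological date ranges, genetic sex, uniparental
haplogroups, coverage, approximate site coordinates) so everything
computable from metadata alone runs on real numbers.

Ancient samples are represented as pseudo-haploid calls: at each SNP one
random sequencing read's allele stands in for the diploid genotype, so
calls take only the homozygous codes 0 and 2. This representation, not a
nuisance detail, shapes several methods below (allele counting in group
frequencies, the kinship mismatch statistic, the absence of
heterozygosity-based bias corrections).

## The synthetic-data generator

Population allele frequencies follow the Balding–Nichols model: given a
parent frequency $p$ and drift parameter $F$, a descendant's frequency is
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, which
has mean $p$ and variance $F\,p(1-p)$ — the minimal model consistent with
the expectations that f-statistics rely on. Coalescent simulation would
add realism (linkage, genealogical noise) that none of the implemented
estimators consumes, so it is deliberately avoided. Ancestral frequencies
default to Uniform(0.05, 0.95), mimicking a MAF-filtered capture panel
(panels used for this kind of analysis are ascertained for common
variation; a MAF > 0.05 filter is applied before PCA in the workflow this
package follows). Drift parameters below $10^{-7}$ are treated as exactly
zero so that zero-drift populations copy their parent.

Admixed populations take the weighted mean of their sources' frequencies
before their own drift. Sex-biased admixture uses the standard uniparental
accounting: if source $i$ contributes fractions $m_i$ and $f_i$ of the
male- and female-side ancestry, its autosomal weight is $(m_i+f_i)/2$ and
its chrX weight $(m_i+2f_i)/3$, because two-thirds of X-chromosome
ancestry traces through females. The chrX track is simulated as an
independent frequency set with the chrX weights; there is no
within-chromosome linkage anywhere in the generator, which is why
jackknife blocks are defined on SNP index rather than genetic distance.

Genotype sampling is Binomial(2, p) for diploids and a single
Bernoulli(p) draw coded {0, 2} for pseudo-haploids, with independent
per-call missingness. Coverage-correlated missingness, post-mortem damage,
contamination and reference bias are *not* emulated; tests passing on this
generator therefore validate the estimators' logic and calibration, not
their robustness to those artefacts.

Pedigrees track two haplotypes per founder; offspring inherit one random
allele per parent per site; a duplicated sample is a second, independent
pseudo-haploid resampling of one diploid genome — exactly the situation of
one individual sequenced twice.

X/Y read counts are Binomial with chrY fraction `q_male = 0.25` for XY and
`q_female = 0.002` (residual mismapping) for XX individuals. chrY call
tables place `n` informative positions on each branch of a small
haplogroup tree; a male's lineage branches are called derived with
probability `1 − flip_error`, everything else with probability
`flip_error`. An XX individual's chrY "coverage" is spurious mismapping:
positions are called at rate 0.002 (matching `q_female`, for internal
consistency) and carry the derived allele only at the flip-error rate,
since mismapped reads carry the reference allele.

## f-statistics

Group frequencies count observed alleles by ploidy: a pseudo-haploid
sample contributes one allele observation per covered SNP, a diploid two.
f4(A,B;C,D) is the mean over complete-case SNPs of $(a-b)(c-d)$;
outgroup f3(O;A,B) the mean of $(o-a)(o-b)$. No small-sample bias
correction is applied: the cross-products are unbiased in the population
frequencies, and the heterozygosity correction used elsewhere for f3 is
ill-defined when a group contributes a single pseudo-haploid observation.
This is a documented divergence from ADMIXTOOLS' corrected f3; outgroup-f3
*comparisons* across panel groups, which is how f3 is used here, are
unaffected by the common bias term.

Standard errors come from a weighted delete-one-block jackknife over
contiguous blocks of 500 SNPs in map order (the weighted form handles the
ragged last block; with equal blocks it reduces to the textbook delete-one
formula, which the test suite checks against a brute-force oracle). The
block size is a configuration default: with linkage-free synthetic data
any blocking is valid, and 500 SNPs keeps at least ~40 blocks in the
smallest simulations.

The cladality screen runs f4(outgroup, T; A, B) over a panel of
comparison groups T and calls the pair (A, B) *cladal* when at least 95%
of panel results satisfy $|Z| \le 3$; significant panel groups are
reported with the sign of their attraction. Both the Z threshold and the
fraction are configuration values with those defaults.

The chrX-versus-autosome contrast computes outgroup f3 for a focal group
against a panel on both tracks, drops panel entries with fewer than 1,000
usable chrX SNPs (sparse chrX intersections make the statistic
uninterpretable), standardises each vector across the panel and reports
$D = z_X - z_{\text{auto}}$: positive for groups to which the focal
population has relatively more affinity through its female ancestors.

## qpAdm

A target $T$ is modelled as $\sum_i w_i S_i$ with $\sum w_i = 1$ against
right populations $r_0, \dots, r_m$. The statistics
$y_j = f4(T, r_0;\, r_0, r_j)$ and $B_{ij} = f4(S_i, r_0;\, r_0, r_j)$
make the admixture identity exactly linear: $y = B^\top w$. All
statistics use the complete-case SNP intersection of every modelled group
(no per-statistic SNP sets), and samples should be pre-filtered to
>100,000 covered SNPs before grouping, mirroring standard practice for
admixture modelling of low-coverage genomes.

Fitting is two-pass generalised least squares. The first pass minimises
the residual under the block-jackknife covariance of $y$ alone — unlike an
ordinary least-squares start, this metric is invariant when a right
population is duplicated, because a duplicated equation carries a
perfectly correlated error and no new information. The residual vectors of
the delete-one-block replicates at the first-pass weights give the
covariance $\Sigma$; the second pass solves the sum-constrained GLS
problem under $\Sigma$ in closed form. Singular covariances (duplicate or
collinear right populations) are handled by spectral pseudo-inversion:
zero-variance residual directions are projected out and their count is
reported. Per-weight standard errors come from delete-one-block refits at
fixed $\Sigma$.

The model test statistic is the minimised quadratic form with
$\text{df} = n_{\text{right}} - n_{\text{left}} + 1$ (the left set counts
the target). Because $\Sigma$ is estimated from a finite number of blocks
$g$, the statistic follows Hotelling's $T^2$ rather than a chi-square;
the p-value therefore uses the exact $F$ transform
$q\,(g-\text{df})/(\text{df}\,(g-1)) \sim F(\text{df},\, g-\text{df})$.
With the plain chi-square the test is measurably anti-conservative at
$g \approx 100$ blocks (circa 8–15% rejection of true models at the 5%
level in simulation); this is a deliberate divergence from ADMIXTOOLS'
chi-square. A model that fits exactly (zero residual, e.g. the target
duplicated among the sources) short-circuits to $p = 1$.

A model is *plausible* when all point estimates lie in $[0,1]$ — the word
is used informally in the literature, so the operationalisation is
explicit here — and *nonrejected* at $p > 0.05$. The model search takes a
named menu of candidate sources per ancestry role, fits every
one-candidate-per-role combination together with all sub-models dropping
one or two roles, and reports both the raw enumeration (a 5 x 3 x 3 menu
enumerates $45 \times 7 = 315$ fits, counting each trio's sub-models) and
the deduplicated source sets actually fitted (95 for that menu). Models
are ranked by p-value with ties broken toward fewer sources; unfittable
models stay in the report with their error.

## PCA and least-squares projection

The PCA model is fitted on reference samples only: per-SNP centring at
the mean dosage, scaling by $\sqrt{\hat p(1-\hat p)}$ with
$\hat p$ floored at $1/(2n_{\text{ref}}+2)$ to keep monomorphic reference
SNPs finite, mean imputation of missing entries *at fit time only*, and
SVD. Eigenvalues are $d_k^2/(n_{\text{ref}}-1)$.

Sparse samples are placed by least squares on their observed SNPs only
(the `lsqproject` semantics): coordinates minimise the squared distance
between the standardised observed dosages and the loadings-spanned
subspace via the normal equations on the observed-SNP submatrix. With no
missingness this equals the direct score exactly; degenerate systems
(fewer observed SNPs than components) fall back to the least-norm
solution and are flagged. Projection uses observed SNPs only, so
missingness does not shrink samples toward the origin; the residual
shrinkage that remains (projections of new samples do not load on
components that overfit reference noise) is inherent to projection and
not corrected.

Distances for the heterogeneity analysis use coordinates multiplied by
their eigenvalues, 25 components by default. The phrase "scaling by the
eigenvalue" admits a $\lambda$ or $\sqrt\lambda$ reading; the literal
$\lambda$ multiplication is the default and the exceedance fraction below
is invariant to any common rescaling, so the choice affects plots more
than conclusions.

One validation choice deserves its own paragraph. "A projected sample
lands inside its source cluster" is only a meaningful check when the
cluster's spread on the leading components is genuine structure. For an
i.i.d. simulated population it is not: the within-cluster spread on any
fixed component is pure binomial sampling noise (about one standardised
unit, independent of SNP count), while the projection error of a sample
observed at a fraction $c$ of SNPs has standard deviation about
$1/\sqrt c$ units — so containment would measure a noise ratio, not
placement quality, and no SNP count changes it. Real reference panels are
admixture clines whose leading-PC spread grows with the number of SNPs.
The projection tests therefore model the reference as a two-axis
admixture cline over three base populations, and sparse test samples are
drawn from the cline's interior; under that (realistic) structure,
projections land inside the reference hull essentially always.

## Heterogeneity in eigenvalue-scaled PC space

Study individuals are binned by the midpoint of their date range into
four contiguous windows on the signed-year axis (BCE negative):
3000–700 BCE, 699–300 BCE, 299 BCE–900 CE and 901–1800 CE. Bins are
lower-exclusive and upper-inclusive (the first bin closed below); this
boundary convention is the one that reproduces the published membership
counts (15, 27, 26, 19) given half-integer midpoints such as −299.5.
Four named individuals are excluded by identifier rather than by midpoint
logic: the published exclusion list is not fully derivable from midpoints
(two of the four fall inside other bins), so an explicit list is the only
faithful encoding.

Geography uses the haversine great-circle distance with Earth radius
6371.0 km. Each bin's geographic concentration is summarised by the
radius of its minimal bounding circle — the smallest spherical cap
containing the members' sites — computed exactly by Welzl's algorithm on
the 3-D unit-sphere embedding (a cap has three degrees of freedom, so a
support set of at most three points determines it; the implementation
assumes point sets within a hemisphere, which geographic site clusters
satisfy). The test suite checks it against exhaustive enumeration of all
two- and three-point circumscribing caps.

The null is built from a reference panel with coordinates: every panel
member whose neighbourhood within the bin's radius holds at least 10
individuals (counting the seed; a strict more-than-10-others variant is
available behind a flag, since published descriptions of this procedure
are ambiguous by one) is an eligible subset seed, up to 100 seeds are
drawn without replacement, and each subset is the seed's whole
neighbourhood. The study set's mean pairwise distance in scaled PC space
is compared with the subset means; the *exceedance fraction* is the share
of subsets at least as heterogeneous as the study set. Gaussian KDEs of
all distance sets are evaluated on a shared grid (Silverman bandwidth by
default, recorded in the report; the grid extends three bandwidths beyond
the data so densities integrate to one), with an optional density cutoff
for display.

## Kinship

Pairwise mismatch rates P0 are computed on MAF > 0.1 sites in 1 Mb
windows of physical position, dropping windows with fewer than 10
co-observed sites. Scores are normalised by the cohort median of per-pair
mean P0 — the expected value of an unrelated pair provided most pairs are
unrelated, and robust to a few relatives (the reason for the median
rather than the mean). Classes follow the published READ thresholds on
the normalised score: < 0.625 identical/twin, < 0.8125 first degree,
< 0.90625 second degree, otherwise unrelated; the thresholds halve the
expected allele-sharing deficit degree by degree. A cohort whose scores
are degenerate (all equal, or a zero median) has no unrelated baseline;
classification is suppressed with a warning rather than guessed.
Distinguishing parent–offspring from siblings is out of scope (it needs
IBD-segment or genotype-likelihood modelling); the class is "first
degree" only. Identical pairs can be merged into a consensus
pseudo-haploid sample: agreeing calls are kept, conflicts become missing,
one-sided observations are kept.

## Sexing and chrY haplogroups

The Ry statistic $n_Y/(n_X+n_Y)$ is compared to two thresholds via a 95%
Wilson score interval (chosen over the Wald interval for its behaviour at
small counts): XY when the interval lies above 0.075, XX when below
0.016, ambiguous otherwise. Both thresholds follow the read-fraction
sexing convention for shotgun data and are configurable. The assignment
is monotone in $n_Y$ at fixed total.

chrY haplogroup scoring tallies derived proportions per haplogroup over
informative positions. A haplogroup is a candidate only with at least 3
called positions *and* a strict majority of them derived — the
minimum-evidence rule that keeps XX individuals (whose sparse spurious
chrY calls carry the ancestral allele) unassigned, matching the empirical
observation that female samples never yield a consistent haplogroup.
Without a tree the candidate with the highest proportion wins (ties to
the larger call count, unresolved ties flagged). With a tree, lineage
accumulation applies: a true carrier is derived along its whole root
path, so all its ancestors are candidates with statistically
indistinguishable proportions, and a noisy argmax would pick an arbitrary
lineage member. The assignment is therefore the *deepest* candidate whose
called ancestors are all majority-derived. In simulation (50 informative
positions per branch, 5% flip error) this recovers the true terminal
haplogroup in over 95% of replicates, where flat argmax recovers it about
a third of the time.

## Problem sizes and calibration checks

The test-suite and acceptance-script simulations use: qpAdm recovery at
50,000 SNPs, 5 pseudo-haploid samples per population, 10 right
populations, 50 replicates (weight coverage within ±2 SE and
non-rejection both ≥ 90%); heterogeneity at 3,000 SNPs with 60 reference,
12 study and 40 panel samples, 50 replicates (exceedance fraction 0 in ≥
95%); kinship at 20,000 MAF-filtered sites, 40 replicates (pair-level
accuracy ≥ 95%); sexing at 10,000 reads (error-free in 100 draws); chrY
recovery over 200 replicates. These sizes were chosen as the smallest at
which the published-scale behaviours are expected to be stable, and the
per-module documentation states the corresponding defaults.

## Known limitations

* No linkage anywhere: jackknife blocks are index-based and the generator
  cannot probe LD-sensitivity of any estimator.
* No damage, contamination or reference-bias model; QC steps that detect
  those artefacts are upstream of this package's scope.
* qpAdm uses the complete-case SNP intersection only; an "allsnps"-style
  per-statistic mode is not implemented.
* The PCA projection applies no shrinkage correction; comparisons mix
  reference scores and projected coordinates at the user's risk (the
  heterogeneity analysis compares projected samples with projected
  samples, which is unaffected).
* Kinship classification assumes a mostly-unrelated cohort for its median
  normalisation and reports only degrees up to two.
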