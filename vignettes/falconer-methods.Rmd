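---
title: "Methods: single-locus effect decomposition for pediatric SNP cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-locus effect decomposition for pediatric SNP cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falconer)
```

# The analysis chain

`falconer` implements the statistical chain of a candidate-gene
cross-sectional study in prepubertal children: anthropometric
standardisation, case/control classification, per-locus frequency and
Hardy–Weinberg testing, case-control association, genotype-stratified
phenotype contrasts, and the quantitative-genetic effect decomposition that
is the package's core. This vignette states the models, the conventions
chosen where the design was genuinely open, and what the synthetic-data
tests do and do not establish.

# Anthropometric standardisation

**BMI** is weight/(height in m)². Heights below 50 are rejected rather than
silently rescaled: in a pediatric table a value like 1.41 is almost
certainly metres, and a silent conversion would corrupt downstream
z-scores. This is a deliberate loud-failure choice.

**LMS z-scores.** A growth reference supplies, per sex and age, the Box-Cox
power L (unitless), median M (units of the measure) and coefficient of
variation S (unitless); then z = ((X/M)^L − 1)/(L·S). When |L| ≤ 1e−8 the
Box-Cox limit z = log(X/M)/S is used; the threshold is far below any real
reference value of L and exists purely to keep the formula numerically
defined. L, M and S are interpolated linearly in age, each parameter
independently — the convention of published reference tables, which
tabulate the three curves on a common age grid. Ages within one grid step
outside the table use the boundary row; anything further is an error naming
the covered range. Ages in days are converted to months with the mean month
length 30.4375 days.

The reference tables are **pluggable inputs**, not embedded constants: real
analyses should supply their national or international reference. The
packaged toy reference (L = −1.6, S = 0.11, M rising gently with age,
girls 0.2 units above boys) is self-consistent and spans ages 90–150
months; it exists so the test-suite needs no download, not as a usable
growth standard.

**Weight category.** A child is `overweight_obese` (the case group) when
BMI is at or above the sex- and age-interpolated overweight cutoff of an
IOTF-style table; overweight and obese are merged, as the case/control
design requires. A BMI exactly at the cutoff classifies as case: the
boundary must go somewhere, and a deterministic ≥ rule is preferred to
round-half behaviour.

**HOMA-IR** is insulin (µU/ml) × glucose (mg/dl) / 405, bilinear in its
inputs and zero when either is zero.

# Frequencies and Hardy–Weinberg testing

Genotype calls are unordered allele pairs; "A/G" and "G/A" are the same
call, enforced by canonical sorting at read time. Major/minor orientation
comes from the declared SNP panel; when undeclared it is inferred from
observed allele frequency with lexicographic tie-breaking, so results are
reproducible even at exactly 50/50. Allele counts always equal twice the
genotype total by construction, and the unit tests assert this conservation
on every counting path.

Two Hardy–Weinberg tests are computed side by side and both reported,
because published tables rarely state which variant produced them:

- **Pearson chi-square** against expected counts (p², 2pq, q²)·n, df = 1,
  no continuity correction;
- the **exact conditional test**: given the allele counts, the probability
  of all heterozygote configurations no more probable than the observed
  one. The implementation walks the heterozygote counts of fixed parity
  with the standard log-probability recurrence
  P(h+2)/P(h) = 4·n_AA(h)·n_aa(h)/((h+1)(h+2)), which is overflow-safe at
  the cohort sizes involved (hundreds). A relative slack of 1e−12 guards
  the ≤ comparison against floating-point ties. The test-suite proves the
  recurrence equal (to 1e−12) to an independent direct log-factorial
  enumeration for totals up to 200.

The exact p is the headline value: on the packaged reference counts it
reproduces the published control-group deviations at all printed precisions,
which the chi-square variant does not quite do. Monomorphic samples are in
equilibrium by convention (p = 1).

**Case-control association** is the Pearson chi-square, no continuity
correction, on the 2×2 allele table or the 2×3 genotype table. Genotype
columns empty in both groups (a rare-allele locus often has zero minor
homozygotes) are dropped with df reduced; a table degenerating to a single
column yields a flagged not-computable result rather than an exception,
because a rare allele is an expected feature of the design, not a data
error.

# Genotype-stratified contrasts

Phenotype means of the heterozygote and minor homozygote are contrasted
against the wild-type (major) homozygote with a Welch 95% confidence
interval on the mean difference and a rank-based p value: Dunn's z on mean
ranks over the genotype groups, with tie-corrected variance, multiplied by
the number of per-SNP comparisons (Bonferroni) and capped at 1. The
rank-based default follows the "distributions (mean ranks) vary between
groups" convention of descriptive tables in this field; pairwise Welch
t-tests are selectable (`method = "welch"`) for users who prefer the
parametric reading. Multiplicity is corrected **within a SNP × phenotype
family only** — a five-SNP candidate panel is not a genome-wide scan, and
per-table correction mirrors how such studies report.

Genotype classes with fewer than two observations are excluded from the
comparisons but their summaries are still printed (letter "−"): a
single-child class has a mean worth displaying and no variance worth
testing. Compact letters are the maximal cliques of the
"not-significantly-different" graph, computed exactly (at most three
genotype classes).

# The Falconer decomposition

With genotype means (mean₁, mean₂, mean₃) for (major homozygote,
heterozygote, minor homozygote) and major/minor frequencies (p, q):

- midpoint m = (mean₁ + mean₃)/2, additive a = mean₃ − m, dominance
  d = mean₂ − m; the three means reconstruct exactly as (m − a, m + d,
  m + a), and the test-suite asserts this inversion on 1000 random
  instances, along with sign equivariance (negating the phenotype) and
  allele-orientation equivariance (swapping major/minor negates a and α).
- α = a + d(p − q) is the average effect of substituting a major for a
  minor allele; α₁ = p·α the minor-allele average effect; both oriented
  toward the minor allele.
- two "population mean" conventions exist in the literature. The value
  reported under `population_mean` is the homozygote midpoint m, which is
  what published effect tables of this design print; the frequency-weighted
  Hardy–Weinberg mean m + a(q − p) + 2pqd is additionally reported as
  `pop_mean_hw` so no information is lost.
- the published "average effect of changing to minor allele" row could not
  be reproduced from any standard substitution-effect formula with any
  allele-frequency source tried during development; the package reports α
  under the `aecme` name and the reproduction report flags the printed row
  as non-matching rather than guessing an undocumented variant.

**Dominance type** is classified from r = |d/a| with a relative tolerance
band, default 0.25: |d| ≤ 0.25|a| is no dominance, r within [0.75, 1.25] is
complete dominance, below partial, above (including a = 0, d ≠ 0)
overdominance. The band is a package decision — the underlying theory gives
no numeric rule — and 0.25 is wide enough that sampling noise in d/a does
not flip labels gratuitously, yet reproduces all four published reference
labels from their derived (a, d) pairs. It is configurable (`tol`).

**Effect grading** uses |x| against cutoffs 0.05 / 0.2 / 0.8 (SD units when
grading zBMI effects), signed by direction. The printed inequalities of the
convention are strict on both sides, leaving boundaries undefined;
boundaries are assigned upward (0.05 → weak, 0.2 → medium, 0.8 → strong),
documented here as the package's convention. The graded quantity defaults
to α₁ — the choice that reproduces the published qualitative labels from
that table's own α₁ row — and is configurable (`grade_on`).

The `falconer()` fit computes class means, their SEs, the residual SD and
the decomposition from individual-level data; `falconer_decompose()` is the
shared kernel that table-reproduction mode also uses on pooled printed
means. Pooling is the exact n-weighted mean. A missing genotype class
yields a partial result carrying whichever quantities remain defined
(midpoint and a need only the homozygotes), flagged not-computable; a
present mean with n = 0 is a contradiction and errors.

# The synthetic-cohort generator

The generator exists so that every stage of the chain is testable against a
known truth. It emulates, under a single mandatory seed:

- a cohort of 773 children (381 boys, 392 girls) aged 9.0–10.6 years;
- five biallelic SNPs drawn independently in Hardy–Weinberg equilibrium at
  minor-allele frequencies 0.47, 0.46, 0.01, 0.21, 0.09, thinned by
  per-SNP call rates 617/773, 530/773, 437/773, 352/773, 272/773 — the
  coverage pattern of a partially genotyped candidate panel. The
  0.01-frequency locus deliberately yields zero minor homozygotes in most
  runs, exercising the degenerate-class paths;
- a latent zBMI that is Normal(0.65, 1.11) plus, per SNP, the planted
  genotype effect (−a, +d, +a) plus Normal(0, 0.25) noise, clipped to
  [−4, 4] to keep the Box-Cox inverse defined;
- BMI built backwards through the toy LMS reference, weight from BMI and a
  sex-specific Normal height, so the derivation code runs on fully
  consistent inputs;
- ancillary circumferences and biochemistry as documented linear functions
  of the standardised latent z plus Gaussian noise. These give the
  descriptive-table code realistic-looking inputs; **no physiological
  realism is claimed** — in particular no real covariance structure among
  analytes, no measurement-error model, no skewness beyond the log-normal
  insulin/leptin;
- independent missingness at rate 0.15 on optional fields.

The overweight cutoff of the toy IOTF table is placed at the 70th
percentile of the full generative latent distribution (baseline plus the
planted effects' mean and variance, Gaussian approximation), so the case
fraction is ≈ 0.30 by construction rather than by tuning. Because the toy
M curve is linear in age with constant L and S, the BMI cutoff is exactly
linear in age and the two interpolation grids (months for LMS, half-years
for cutoffs) introduce no classification disagreement.

What passing tests show: the estimators recover planted (a, d) within
sampling error, the exact HWE test is calibrated on HWE draws, the
case-control test holds its nominal type-I error, and contrast intervals
cover at their nominal rate — all **under the generator's assumptions**
(independent loci, Gaussian noise, marginal single-locus effects). They do
not certify behaviour under population stratification, genotyping error,
informative missingness, or real biochemical covariance, none of which the
generator models.

# Problem sizes and numerical choices

The test-suite and the acceptance script use: 1000 random instances for the
decomposition inversion/equivariance properties; 1000 null replicates at
n = 300/300 for type-I calibration; 500 replicates for contrast-interval
coverage and contrast unbiasedness; 200 replicates for the power-style
checks; n = 10⁴ for planted-effect recovery and n = 10⁵ for genotype
frequency convergence. These sizes put Monte-Carlo error comfortably below
the asserted margins (e.g. ±1.5 percentage points around a 5% rejection
rate at 1000 replicates is ≈ 2.2 binomial SDs) while keeping the default
run short.

Reproduction of published values is checked at each cell's printed number
of decimal places, with "match" meaning agreement within one unit in the
last printed digit. The one-ulp slack is needed because published rounding
is not always half-even from the underlying value (a p of 0.18954 printed
as 0.189); anything further off is flagged, never silently accepted.

# Known limitations

- Single-locus marginal analysis only: no covariate adjustment, no
  logistic-regression odds ratios, no haplotypes, epistasis, or
  variance-component/heritability estimation.
- Biallelic SNPs only; multiallelic VCF records are rejected loudly, and
  VCF support is read-only (CHROM/POS/ID/REF/ALT + GT).
- No pedigree structure and no genotype imputation; missing calls simply
  reduce the per-SNP analysis n.
- The Welch interval and the rank-based p answer slightly different
  questions (means vs distributions); the contrast output deliberately
  shows both rather than forcing one reading.
- Grading and dominance labels inherit the arbitrariness of their cutoffs;
  both are configurable, and the defaults are documented conventions, not
  estimates.
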