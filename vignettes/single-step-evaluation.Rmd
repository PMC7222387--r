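---
title: "Single-step genomic evaluation: models, matrices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation: models, matrices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the animal model and its Gibbs sampler, the pedigree, genomic
and combined relationship matrices, the evaluation metrics, and — because
several choices were genuinely open — the reasoning behind the defaults.

## The animal model

Every trait is analyzed under

$$ y = Xb + Z_1 h + Z_2 a + e $$

with fixed effects $b$ (unordered factors such as year, appraiser, dam
age, sex and strain), a random flock effect $h \sim N(0, I\sigma_h^2)$, an
additive genetic effect $a \sim N(0, K\sigma_a^2)$ with $K = A$ (pedigree
only) or $K = H$ (single step), and residuals $e \sim N(0, I\sigma_e^2)$.
Heritability is defined against the total of the three modeled variances,
$h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_h^2 + \sigma_e^2)$.

Assumptions worth stating explicitly: one record per animal (repeated
records are supported by the design matrices but no permanent-environment
effect is modeled), no maternal effects, single-trait analyses only, and
flocks exchangeable with a common variance.

## Relationship matrices

**A and its inverse.** `compute_A()` uses the tabular recursion; diagonals
are $1 + F_i$. `compute_A_inverse()` never forms the dense matrix: it adds
Henderson's per-animal contributions $1/d_i$, where the Mendelian-sampling
variance $d_i$ comes from the Meuwissen–Luo recursion on parental
inbreeding ($d_i = 0.5 - 0.25(F_s + F_d)$, with the unknown-parent
convention $F = -1$ so that a missing side contributes nothing). Unknown
parents are unrelated founders; unknown-parent groups and metafounders are
out of scope. Because recording systems often trace each animal only a few
generations back, `truncate_pedigree()` exposes an optional
generation-truncation preprocessing step; the default is to use the full
supplied pedigree.

**G.** VanRaden centering with frequencies observed in the genotyped set —
the conventional reading when no base-population frequencies are
available; a supplied-frequency path exists and is what the full-sib
simulation tests use, since frequencies observed *within* a family re-base
the relationships. Missing calls surviving QC are mean-imputed to $2p_j$,
i.e. contribute zero after centering.

**Quality control** applies, in a fixed and logged order: animal call rate
$\ge 0.90$, SNP call rate $\ge 0.90$, monomorphic removal, MAF $\ge 0.01$,
and an exact Hardy–Weinberg test at $p < 10^{-6}$. The HWE test enumerates
the conditional distribution of the heterozygote count given the allele
counts (two-sided: sum of outcome probabilities not exceeding the observed
one). The order matters for attribution of removals, which is why the
report records counts per stage.

**H and its inverse.** The combined matrix places (blended) $G$ in the
genotyped block and projects it onto ungenotyped relatives through
$A_{12}A_{22}^{-1}$. The inverse is assembled sparsely as $A^{-1}$ plus the
genotyped-block correction $G^{-1} - A_{22}^{-1}$. Two decisions here:

* *Sign of the correction.* The genotyped-block correction occasionally
  appears in the literature typeset with a plus sign; the package uses
  $G^{-1} - A_{22}^{-1}$, the standard single-step result. The opposite
  sign fails the basic degeneracy test — with $G = A_{22}$
  the combined matrix must collapse to $A$ — which the test suite checks
  bit-for-bit alongside the empty-genotype case $H = A$.
* *Blending.* $G^* = (1-w)G + wA_{22}$ with default $w = 0.05$ guarantees
  a positive-definite genomic block (raw $G$ is singular whenever there
  are more genotyped animals than informative SNPs). $w = 0$ disables
  blending and turns a singular $G$ into an explicit error. No
  scaling/tuning of $G$ to the scale of $A_{22}$ is applied by default,
  and the $\tau/\omega$ weights of the correction are fixed at 1;
  both would be sensitivity analyses, not defaults, for this workflow.

## The Gibbs sampler

Location effects are updated single-site from their normal full
conditionals in a fixed order (fixed effects, then flock, then animal);
variances follow from scaled-inverse-chi-square full conditionals, with
the animal quadratic form $a'K^{-1}a$ evaluated against the sparse
inverse. The default priors are flat for variances (degrees of belief
$-2$, scale 0, the convention of the widely used samplers in this field);
they are proper-prior configurable, and a prior-predictive test verifies
that with no data the variance draws reproduce a proper prior. All
randomness flows through R's RNG, so a seed makes runs bit-reproducible;
two chain configurations are bundled — a desk-scale default
(10,000/1,000/10) and a long reference configuration (100,000/10,000/50).

Identifiability choices: fixed effects use corner-point constraints with
levels sorted by label; a fixed effect observed in a single class is
constrained out with a warning; records with missing labels are dropped
with a logged count; flock classes without records are dropped.

**Threshold traits.** Ordinal scores (4–5 point scales in the motivating
application) are modeled through a latent liability cut at ordered
thresholds, sampled by data augmentation with truncated normals. The key
identification decision: the first threshold is fixed at 0 and, for three
or more categories, the second at 1, leaving $\sigma_e^2$ estimable. The
alternative — fixing $\sigma_e^2 = 1$ and sampling all thresholds — is
equivalent up to scale, but reporting free residual variances for ordinal
traits requires the two-threshold constraint, and heritability is
invariant to the choice. Binary traits fix $\sigma_e^2 = 1$ instead.
Remaining thresholds are sampled uniformly between the extreme liabilities
of adjacent categories; this mixes slowly at large $n$ (a known property
of the scheme), which is why chain length, not thinning, is the lever to
pull for ordinal traits. An unobserved category is an error instructing a
merge, not a silent repair.

## Evaluation metrics

Accuracy is $\sqrt{1 - \mathrm{SEP}^2/\sigma_a^2}$ with SEP the posterior
standard deviation of the animal's additive effect and $\sigma_a^2$ the
posterior mean from the same fit. The quantity $1 -
\mathrm{SEP}^2/\sigma_a^2$ without the square root is the *reliability*;
published accuracy formulas sometimes omit the root, but the square-root
form is the standard definition of accuracy and is what the package
computes. Monte Carlo noise can push $\mathrm{SEP}^2$ above $\sigma_a^2$
for uninformative animals; accuracy is then clipped to 0 and the count
reported.

The model comparison reports the per-animal-relative gain
$\Delta\mathrm{acc} = 100\cdot\mathrm{mean}((r_H - r_P)/r_P)$ (animals
with $r_P = 0$ excluded and counted) *and* the ratio-of-means variant,
because published gain figures are generally not reproducible from
printed mean accuracies under either definition alone; both Pearson and
Spearman correlations of the two EBV vectors are emitted for the same
reason. The sign of the ratio-of-means variant is antisymmetric under
swapping the two models.

The Geweke diagnostic compares the means of the first 10% and last 50% of
a chain, standardized by AR-spectral estimates of the window variances;
its nominal 95% coverage on stationary chains is verified by simulation
(500 chains), and it agrees with the reference CODA implementation to
z-score resolution (window endpoint conventions differ by one sample).

## The synthetic-data generator

Real single-step evaluation datasets of the motivating kind are not
public, so the generator emulates their structure: discrete generations
under polygynous random mating (a small sire pool, dams sampled with
replacement), genotyped animals concentrated in the youngest two cohorts,
SNPs gene-dropped through the pedigree from founder frequencies uniform on
(0.01, 0.5), and phenotypes built directly from the generative model with
known true parameters. Breeding values can be drawn either through the
pedigree (Mendelian-sampling recursion, exactly $\mathrm{Var}(a) =
\sigma_a^2 A$) or as $Mu$ from SNP effects; both paths recover the same
heritability when fitted with the matching relationship matrix, which is
tested.

Default scenario sizes are a deliberate desk-scale choice: 3,000 animals
(600 founders + 4 × 600), 1,000 genotyped, 2,000 SNPs — about one tenth
of the motivating population, preserving its ~threefold excess of
ungenotyped over genotyped animals. The flock effect keeps 156 classes,
matching the motivating recording scheme rather than scaling down: the
number of levels of a random effect governs how well its variance is
identified, and with only ~16 levels the flat-prior posterior mean of
$\sigma_h^2$ is noticeably inflated, which would contaminate heritability
recovery for reasons unrelated to the genetic model. Fixed-effect class
counts *are* scaled down (year 8, appraiser 6, dam age 4, sex 2,
strain 4) to stay estimable at one tenth of the data volume. True
fixed-effect coefficients are evenly spaced, sum to zero within each
factor, and span half a phenotypic standard deviation. Ordinal thresholds
default to equal-mass cuts of the realized liability.

What the generator does **not** emulate — and therefore what passing
tests do not certify about real data: linkage disequilibrium among SNPs
(loci segregate independently), selection and assortative mating across
generations, genotyping error and pedigree misassignment, heterogeneous
flock sizes, and genotype-by-environment interaction. Conclusions about
LD-dependent behavior (e.g. imputation, chip ascertainment) are out of
scope by construction.

## Numerical choices and degenerate inputs

* Topological sorting uses a stable Kahn ordering with input position as
  tie-break, so outputs are reproducible and row-order invariant; cycles
  are reported with an offending animal named.
* $A^{-1}$ and $H^{-1}$ are sparse (`Matrix`); dense algebra is reserved
  for $A$, $G$ and block inverses at desk scales (≤ ~50k animals for $A$,
  a few thousand genotyped for $G$).
* Symmetric inverses go through Cholesky factorizations with explicit
  errors naming the offending matrix.
* Oracle tests pin the sparse routes to dense inversion (≤ 500 animals,
  1e-6), A to gene-dropping Monte Carlo (3 SE), and the HWE test to an
  independent recurrence-based enumeration over *all* genotype tables
  with n ≤ 200.
* Chain-length defaults used by the test suite and the acceptance script
  are stated there explicitly; parameter-recovery checks run the full
  3,000-animal scenario for heritability and a reduced 500-animal
  scenario (20 replicates) for the accuracy comparison.

## Known limitations

Single-trait only; no REML (sampling-based inference was the point); no
APY or other large-scale approximations of $H^{-1}$, so the genotyped
count is limited by the dense correction block; threshold-model threshold
sampling mixes slowly for large category counts; accuracy is computed
from posterior prediction error, not from forward cross-validation, so it
measures model-internal information, not realized predictive ability.
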