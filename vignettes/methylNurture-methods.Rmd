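---
title: "Separating direct and indirect polygenic effects on the offspring methylome"
author: "methylNurture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct and indirect polygenic effects on the offspring methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylNurture)
```

## The scientific problem

Parents shape their children twice over: once by transmitting half of
their alleles, and once by creating the environment the child grows up
in. Because the environment parents provide is itself influenced by
heritable parental traits, a parental genotype can leave a mark on the
offspring phenome without ever being transmitted — *genetic nurture*, or
an indirect genetic effect. This package implements an analysis that asks
whether one route for such indirect effects is the offspring methylome:
DNA methylation measured in children, regressed simultaneously on the
child's own polygenic scores (PGSs) and on the mother's and father's PGSs
for the same traits.

The key identification idea is the trio design. Conditional on the
offspring's own PGS, any residual association between a *parental* PGS
and offspring methylation cannot be explained by transmitted alleles at
the scored loci; it points to the environment the parent provides (or to
other processes that correlate parental genotype with offspring
methylation, such as assortative mating — see Limitations).

## The model

For offspring $j$ in family $i$, the residualized methylation value
$Y_{ij}$ at one CpG probe is modelled, across $N$ traits, as

$$
Y_{ij} = \mu
  + \sum_{t=1}^{N}\left(
      \delta_t\,\mathrm{PGS}^{(t)}_{ij}
    + \alpha_{m,t}\,\mathrm{PGS}^{(t)}_{m(i)}
    + \alpha_{p,t}\,\mathrm{PGS}^{(t)}_{p(i)}\right)
  + \beta_1 D_{2,ij} + \beta_2 D_{3,ij} + \varepsilon_{ij},
$$

where $\delta_t$ is the direct effect of the offspring's own score for
trait $t$, $\alpha_{m,t}$ and $\alpha_{p,t}$ are the maternal and
paternal indirect effects, and $D_2$, $D_3$ are dummies for the second
and third methylation dataset (dataset 1 is the reference). With six
traits this is a 21-column design: intercept, 18 PGS predictors
(offspring, maternal, paternal for each trait, in a fixed declared trait
order), and 2 dataset dummies. Modelling all traits jointly means each
trait's effects are estimated while controlling for the direct and
indirect effects of the other traits, and avoids a multiplicity penalty
across traits.

Estimation is by Gaussian generalized estimating equations (GEE) with
identity link, one fit per probe, written from first principles in
`fitGeeProbe()`/`fitGee()`. Families are the clusters: twins share a
family environment and MZ twins share a genome, so observations are not
independent. Coefficient standard errors come from the cluster-robust
sandwich

$$
\widehat{\mathrm{Var}}(\hat\beta) = B^{-1}\!\left(\sum_i
  X_i^\top V_i^{-1}\hat e_i \hat e_i^\top V_i^{-1} X_i\right) B^{-1},
\qquad B = \sum_i X_i^\top V_i^{-1} X_i ,
$$

with the meat summed over families. Under the default independence
working correlation the point estimates are exactly OLS and the whole
probe panel is fitted with one shared factorization; an exchangeable
working structure is available and reproduces the independence fit in
the zero-correlation limit. Two-sided p-values use the standard-normal
reference for the robust z, the GEE convention; no small-sample degrees-
of-freedom correction is applied. With many hundreds of family clusters
this is accurate at conventional levels, but the robust z is mildly
anti-conservative in the extreme tails when clusters are few — another
reason the package's own calibration checks use large simulated cohorts.

A probe's fit is flagged non-converged when its values are non-finite,
the design is rank-deficient, or the exchangeable iteration fails to
settle; non-converged probes are counted and carried through the
bookkeeping (total = successful + non-converged) but excluded from
inference.

## Preprocessing

The methylation matrix enters as beta-values (methylated/total signal,
in $[0,1]$) for offspring samples and moves through a fixed state
machine, `raw -> masked -> imputed -> residualized`, enforced by the
`MethylExperiment` container:

1. **Manifest QC** (`qcFilter`): drop probes flagged cross-reactive,
   SNP-overlapping, or on a sex chromosome, and probes with success rate
   strictly below 0.95 (the boundary is kept). Intensity-level QC is out
   of scope; the manifest flags stand in for it.
2. **Outlier masking** (`maskOutliersIqr`): per probe, values outside
   $[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$ are set missing.
   Quantiles use linear interpolation between order statistics (R type
   7), computed once on the original values — a single pass, so masking
   one value cannot cascade. The quantile definition is configurable
   because upstream tools do not pin one down.
3. **Imputation** (`imputeMissing`): probes missing in more than 5% of
   samples are dropped (strictly more; "up to 5%" is kept). Remaining
   gaps are probe-mean filled by default; an optional truncated-SVD
   refinement iterates a low-rank reconstruction for users who want a
   PCA-style fill. Probe-mean is the tested default because a component
   count cannot be motivated a priori. Masking precedes imputation; the
   reverse order would let imputed values influence outlier bounds.
4. **Residualization** (`residualizeMethyl`): per probe, OLS residuals
   on sex, age, epithelial and NK cell proportions, array row, and
   bisulfite plate. The dataset indicator is deliberately *not*
   residualized out here because the association model carries dataset
   dummies itself. Residualization is a projection, so it is idempotent,
   and rank-deficient covariate designs abort with the collinear columns
   named.
5. **Variance filtering** (`selectTopVariance`): keep the
   $\lfloor q M\rfloor$ most variable probes ($q = 0.10$ by default;
   728,899 probes would yield exactly 72,889). The most variable probes
   are the most reliable, and the cut sharply reduces the multiplicity
   burden. Ties break lexicographically by probe id for determinism.

Polygenic scores are prepared separately (`standardizePgs`,
`imputeParentPgs`): per trait and role, observed scores are residualized
on two genotyping-platform dummies and ten genetic principal components,
scaled to zero mean and unit variance, and only then are missing parental
scores set to zero (the mean) and flagged. Standardizing before imputing
keeps the observed-score scale intact; the reverse order would shrink the
variance of every score. Zero-imputation of a parent biases that parent's
indirect-effect estimate toward zero (classical measurement-error
attenuation); the simulator lets users quantify that attenuation, and the
package does not attempt to correct it.

## Multiple testing

Retained probes are highly correlated, so a Bonferroni correction on the
raw probe count would be needlessly severe. `effectiveTests()` computes
the eigenvalue spectrum of the probe-by-probe Pearson correlation matrix
and applies Nyholt's effective number of tests,

$$ M_\mathrm{eff} = 1 + (M-1)\left(1 - \frac{\mathrm{Var}(\lambda)}{M}\right), $$

with the sample variance of the eigenvalues (denominator $M-1$). When
probes outnumber samples the nonzero spectrum is computed from the dual
sample-by-sample cross-product of the row-standardized data — identical
nonzero eigenvalues at a fraction of the cost — and zeros are appended.
$M_\mathrm{eff}$ is rounded *up* before dividing the family-wise level
(the conservative direction; e.g. $0.05/1850 = 2.7\times10^{-5}$). The
Li–Ji refinement is available as an option but Nyholt is the default.
The decomposition requires the imputed (complete) matrix; a
pairwise-complete correlation path is deliberately not offered. Note
that with $n$ samples the correlation matrix has rank below $n$, so
$M_\mathrm{eff}$ is bounded by the sample count on real panels.

Significant (probe, predictor) pairs are classified by `classifyHits()`
into offspring (direct) versus maternal/paternal (indirect) hits per
trait; `countHits()` produces the role-by-trait table and the
direct/indirect totals, and a probe may legitimately appear for several
predictors.

## The synthetic cohort generator

No individual-level data ship with the package; family methylation data
of this kind are access-controlled. Instead `simulateFamilies()` and
friends generate nuclear twin families with known ground truth so every
stage is exercisable end to end:

* **Genotypes.** Unlinked biallelic loci with frequencies uniform on
  $(0.05, 0.95)$; parents drawn in Hardy–Weinberg proportions under
  random mating; each offspring receives one uniformly chosen allele per
  locus per parent; MZ pairs copy one twin's genome. Mendelian
  consistency holds by construction. The MZ share among twin pairs
  defaults to 0.74 and dataset labels are drawn with shares
  (0.06, 0.75, 0.19), both matching the cohort composition the generator
  emulates.
* **Polygenic scores.** True scores are weighted dosage sums,
  standardized within generation. Under random mating the same-trait
  offspring–parent correlation converges to 0.5 and the spousal
  correlation to 0; the small spousal correlations reported in real data
  (mean ~0.04) are not targeted, as they cannot be distinguished from
  sampling noise there.
* **Methylation.** Per offspring and probe, a Gaussian liability
  $\mu_k + \text{genetic signal} + \text{covariate terms} + u_{ik} + \varepsilon_{ijk}$
  is mapped through the inverse-logit to a beta-value, which keeps the
  $(0,1)$ support without clipping artifacts. The family intercept
  $u_{ik}$ is drawn per probe, giving every probe the same within-family
  liability correlation $\sigma_u^2/(\sigma_u^2+\sigma_e^2)$ (0.5 at the
  defaults) while keeping probes independent replicates. Only probes
  named in an effect spec carry nonzero $\delta$, $\alpha_m$,
  $\alpha_p$. Because the observation model generates unneeded
  correlation structure nowhere else, passing calibration tests here
  says nothing about, e.g., genomic co-methylation blocks, batch
  structure beyond dataset shifts, or cell-composition confounding in
  real data.
* **Missingness.** Parental scores are masked family-wise with marginal
  maternal/paternal missingness 7.9%/18.9% and joint missingness 5.1%,
  reproducing 92.1% of mothers, 81.1% of fathers, and 78.3% of families
  with both parents scored.
* **Seeding.** One master seed fans out to named substreams
  (`childSeed(seed, "genotypes")`, `"covariates"`, `"methylation"`, ...),
  so changing the probe count does not perturb the genotypes and every
  run is bit-reproducible.

A note on scales: effects are defined on the logit (liability) scale.
Since `logit(beta)` recovers the liability exactly, estimator-recovery
checks fit the logit-transformed values; fitting the bounded beta scale
instead attenuates every coefficient by roughly the average logistic
density at the probe's baseline (0.25 at $\mu = 0$). The analysis of
real beta residuals inherits the same interpretation: coefficients are on
the methylation-fraction scale, not the liability scale.

## Verification strategy and problem sizes

The test suite pins every estimator to an independent oracle: OLS for the
independence point estimates, explicit bread/meat arithmetic and an
external HC0 cluster-robust implementation for the sandwich, hand
eigendecompositions and a formula oracle for $M_\mathrm{eff}$, and
brute-force per-probe recomputation for masking, imputation thresholds,
and variance selection. Calibration properties run at sizes chosen to
make Monte-Carlo bands tight while keeping the default test run fast:
2000 families for PGS-correlation and missingness calibration, 2500
null probes at 2000 families for the type-I error of the robust Wald
test (with the naive iid OLS test shown to over-reject on the same
data), and 200 replicates of 500 families for unbiased recovery of
$(\delta, \alpha_m, \alpha_p) = (0.3, 0.2, 0.1)$ with ~95% robust CI
coverage.

## Known limitations

* Indirect-effect estimates are attenuated when parental scores are
  zero-imputed, and confounded by assortative mating if present; the
  generator defaults to random mating and offers no assortment.
* The GEE is marginal: no likelihood, no mixed-model variance
  components, no beta/binomial observation model for bounded values.
* $M_\mathrm{eff}$ depends on the spectral estimate from the available
  samples; with far more probes than samples the true effective test
  count is not identifiable beyond the sample-rank bound.
* The simulator has no linkage disequilibrium, no X-chromosome
  transmission, no co-methylation structure, and technical covariates
  are independent of biology by construction.
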