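---
title: "Methods: variance-components heritability of ECG and CMR ventricular phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-components heritability of ECG and CMR ventricular phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(famh2)
```

`famh2` estimates and compares the narrow-sense heritability of
left- and right-ventricular phenotypes measured by two modalities — 12-lead
electrocardiography (ECG) and cardiovascular magnetic resonance (CMR) — in
panels of extended families. This vignette is the package's account of the
statistical models, the synthetic-cohort generator, and the numerical and
design choices behind them.

## The two heritability models

Both models describe an adjusted phenotype residual $y$ on $n$ individuals
as multivariate normal with a grand mean and covariance

$$V = \sigma^2_g K + \sigma^2_e I, \qquad
  h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e},$$

and differ only in the relatedness kernel $K$ and the fitting criterion.

**Pedigree kernel, maximum likelihood** (`fit_vc_ml()`). $K = 2\Phi$, twice
the kinship matrix computed recursively from the pedigree
($\Phi_{ii} = \tfrac12(1+\Phi_{fm})$,
$\Phi_{ij} = \tfrac12(\Phi_{fj}+\Phi_{mj})$, unknown parents contributing
zero). The general model (polygenic plus individual-specific environment) is
compared by likelihood-ratio test with the nested environment-only null
($\sigma^2_g = 0$). This mirrors the classical family variance-components
analysis implemented by pedigree tools, which fit by ML; the package
documents this choice explicitly because tool names, not criteria, are what
analyses usually report.

**GRM kernel, REML** (`fit_greml()`). $K = A$, the SNP genetic relationship
matrix with entries
$A_{jk} = \frac1m \sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}$ and
the usual distinct diagonal estimator, computed after genotype QC and then
*IBS-thresholded*: off-diagonals below 0.05 are set to zero
(`threshold_grm()`). In samples mixing close and distant relatives, plain
SNP-REML is biased; zeroing background relatedness makes the estimate track
close-relative (effectively identity-by-descent) sharing. The restricted
likelihood profiles out the grand mean; components may be freed to go
negative (`constrained = FALSE`) as long as every rotated variance stays
positive, matching the unconstrained option of standard GREML software.

### One eigendecomposition, one-dimensional search

Writing $K = U D U'$ once per kernel, every likelihood evaluation becomes
$O(n)$ diagonal arithmetic in the rotated basis. We parameterize by $h^2$
and eliminate the mean (GLS) and the total variance
$\sigma^2_p = \sigma^2_g + \sigma^2_e$ (closed form) at their conditional
optima, leaving a smooth one-dimensional profile likelihood on a bounded
interval; Brent search (`optimize()`, tolerance $10^{-8}$) with explicit
endpoint checks then finds the global optimum exactly. We chose this over
iterative average-information/EM updates deliberately: for a single-kernel
model the profiled criterion is identical, there are no convergence
failures to manage, and boundary solutions ($\hat h^2 = 0$ or $1$) are
exact rather than clamped. The likelihood values agree with dense
Cholesky-based evaluations to $10^{-8}$ (tested on $n \le 200$), and for
unconstrained fits the feasible $h^2$ interval is derived from the extreme
eigenvalues so that $V$ stays positive definite.

### Standard errors and tests

Three SE notions coexist and are kept distinct:

* the **Wald-from-LRT** convention $\mathrm{SE} = h^2/\sqrt{\mathrm{LRT}}$
  (`wald_se_from_lrt()`), the convention used when reporting pedigree
  variance-components estimates; undefined (reported missing) when the LRT
  is zero;
* the **expected-information SE** stored on pedigree-ML fits: the Fisher
  information of the $\sigma^2_p$-profiled likelihood in $h^2$, which is a
  deterministic function of the kernel spectrum and $\hat h^2$;
* the **observed-information delta-method SE** stored on REML fits: a
  finite-difference Hessian of the restricted likelihood in
  $(\sigma^2_g, \sigma^2_e)$ mapped to $h^2$, the same role the inverse
  average-information matrix plays in GREML software.

LRT P-values default to the 50:50 $\chi^2_0/\chi^2_1$ boundary mixture
(the null lies on the parameter-space boundary); the plain $\chi^2_1$ tail
is available via `boundary_mixture = FALSE` for concordance with tools that
report it.

## Phenotype derivation and adjustment

`derive_phenotypes()` computes the Sokolow-Lyon and Cornell voltages, their
QRS-duration products, the 12-lead amplitude sum (peak-to-nadir QRS
amplitudes summed over all 12 leads, with its own duration product), ECG LVM
from the sex-specific linear equations, CMR masses (tissue volume ×
1.05 g/cm³), BSA-indexed masses and volumes, ejection fractions, and the
cylindrical chest volume. LVH flags use the published cut-offs
(Sokolow-Lyon 35 mV; Cornell 28/20 mV men/women; duration products
2840/2440 mV·ms) with `>=` at the boundary — the non-LVH side is defined by
values *below* the cut-off, so the boundary itself is classified
hypertrophic; a strict mode is provided since the convention is not forced.

**The voltage-unit question.** The ECG LVM equation's voltage coefficients
(0.026 and 0.020 g per voltage unit) are incompatible with millivolt-scale
Cornell sums (~12 mV): the voltage term would contribute under a gram
against a weight term of ~100 g. The equation's native voltage unit is
evidently finer than the millivolt scale on which lead amplitudes are
tabulated. `ecg_lvm()` therefore exposes `voltage_scale` (default 1.0, i.e.
the equation applied verbatim); the synthetic cohort records in its truth
manifest the scale (default 125) under which the voltage term carries
realistic weight, and the pipeline uses the recorded scale. Analyses of
real data should set the scale to match their amplitude units.

Adjustment follows a fixed stage order: antihypertensive pre-adjustment of
blood pressure (+15/+10 mmHg systolic/diastolic, applied exactly once — the
operation is intentionally not idempotent and is tested as such), then
per-trait Box-Cox transformation, then stepwise selection, then
residualization. Box-Cox maximizes the standard profile log-likelihood
(normal likelihood of the transformed data plus the Jacobian term) over
$\lambda \in [-3, 3]$ via a 601-point grid refined by golden-section/Brent
search to $10^{-4}$; values must be strictly positive (no automatic
shifting — a shifted transform changes the estimand silently). Stepwise is
classic forward-backward OLS with partial $t$-tests at entry/stay threshold
0.01 (single-df partial $F$ equivalently), ties broken by candidate column
order for determinism, perfectly collinear candidates skipped with a
warning, and casewise deletion per phenotype. Whether a trait is Box-Cox
transformed is configurable per recipe, since transform lists in published
pipelines are often trait-specific. Fixed effects are handled entirely by
this upstream residualization; the mixed models fit only a grand mean.

## Genotype QC

`qc_genotypes()` applies, in order: individual call rate < 95% → drop
individual; SNP call rate < 95% → drop SNP; minor allele frequency < 1% →
drop SNP; Hardy-Weinberg exact test $P < 10^{-8}$ computed on founders only
→ drop SNP; heterozygosity outliers ($|F - \bar F| > 3$ SD of the
method-of-moments inbreeding coefficient) → drop individual. Founders-only
HWE avoids relatedness-driven rejections in family data, and the 3-SD
heterozygosity rule pins down an otherwise vague "outlying" criterion; both
are conventional choices and are surfaced as thresholds. The exact test
uses the standard recurrence over heterozygote counts at fixed allele
counts; the test suite checks it against an independent log-factorial
enumeration to $10^{-12}$. QC is idempotent (a second pass removes
nothing), and the report records removals per step in application order.

## The synthetic cohort generator

The generator stands in for undeposited family data; its defaults *are* the
study conditions the analysis assumes.

**Pedigrees.** 116 families built from four templates mixed
50/20/20/10 — nuclear with 2 children, nuclear with 3 children,
three-generation (grandparents, a parent with one full sibling, a
married-in spouse, two grandchildren), and an adult sibship with an
avuncular link — so that sibling, parent-child and uncle/aunt-nephew/niece
pairs all occur. Template counts are apportioned deterministically
(largest remainder), so pedigree *structure* is identical across seeds;
only child sexes and all downstream draws vary. Real recalled cohorts
phenotype whole nuclear families but only part of extended ones, so
nuclear templates are phenotyped in full while grandparents, married-in
spouses and some extended relatives remain in the pedigree unphenotyped;
this yields a phenotyped panel of 440 (within 5% of the 427 target) at a
mean of ~3.8 phenotyped members per family, and maximizes within-family
relational information subject to that mix — consistent with a design
powered for a sampling SE of ĥ² of roughly 7.5 percentage points. The
information ceiling of this structure mix is itself a limitation discussed
below.

**Genotypes.** Gene dropping: founder alleles Bernoulli at per-SNP MAFs
drawn uniformly (default 0.05–0.5), each non-founder allele drawn uniformly
from the corresponding parent's two alleles. The default 2,000 SNPs / 20
causal is desk-scale: GRM-based recovery does not need genome-wide density,
and the suite verifies that the expected GRM of gene-dropped families
equals $2\Phi$ (mean sib-pair entry in [0.45, 0.55] at 5,000 SNPs). No
linkage disequilibrium, X chromosome or genotyping-error model is
simulated.

**Polygenic values.** `pedigree-mvn` mode draws founders
$N(0, \sigma^2_g)$ and each non-founder as the parental mean plus a
segregation deviate of variance $\sigma^2_g/2$, giving exactly
$2\Phi\sigma^2_g$ covariance for non-inbred pedigrees; `genotype-causal`
mode sums standardized causal dosages with
$N(0, \sigma^2_g/n_\text{causal})$ effects. All draws flow from one master
seed through named substreams (`stream_seed()`), so adding a trait never
perturbs another trait's draws and outputs are byte-identical given
(spec, seed).

**Covariates and traits.** Age is $N(59.7, 13^2)$ truncated to [18, 95];
sex is Bernoulli (52.5% female); height (h² 0.75, mean 1.69 m, SD 0.09 m),
weight (h² 0.55, loading on height), chest lateral diameter (h² 0.65,
loading 0.45 on height, ~30.5 cm), blood pressure with a 30%
antihypertensive-treatment prevalence (treated observed values are lower;
pre-adjustment restores them), CMR LV mass (residual h² 0.20 after its
weight/sex covariate part), RV mass (0.44), LV end-diastolic volume (0.40),
and ECG voltages on the Table-style millivolt scale. These centers and
spreads mirror a late-middle-aged, overweight, hypertension-enriched
British family cohort.

**The confounding structure.** The Cornell-lead voltage latent loads on
standardized chest lateral diameter with coefficient 0.8
(`confounder_loading`). The calibration is analytic, not fitted: with the
chest channel (net of height) more heritable (~0.62) than the direct
voltage channel (~0.29), the adjusted-residual heritability of derived ECG
LVM sits near 0.5 unadjusted and attenuates to near 0.3 when chest diameter
joins the adjustment set, and the marginal Spearman ρ between chest
diameter and ECG LVM lands near 0.67. Two structural facts are worth
stating plainly. First, in a linear Gaussian system the chest channel's
heritability net of height cannot exceed the total chest heritability, so
an unadjusted ECG-LVM residual heritability of ~0.6 that attenuates under
chest adjustment is not reachable with chest h² ≈ 0.6; the generator
reproduces the *mechanism and direction* of the attenuation at a slightly
compressed level, not the published pair of values. Second, because the
ECG LVM equation contains body weight and chest size is a function of
stature, the chest/ECG-LVM correlation does **not** vanish when the
voltage loading is set to zero — only the voltage-channel association
(given sex) does; the tests assert exactly that.

**What passing tests do and do not show.** The generator is linear,
Gaussian, additive and free of assortative mating, inbreeding, shared
household environment, dominance, epistasis and measurement drift.
Parameter recovery and coverage on these cohorts validate the estimators
under their own assumptions; they do not certify behaviour under the
non-additive or shared-environment features of real families, which
family-based estimates are known to absorb.

## Numerical choices and degenerate inputs

* Kernel PSD tolerance: the pedigree fit rejects kernels with eigenvalues
  below $-10^{-6}$; the REML fit instead derives feasible component bounds
  from the spectrum, since IBS-thresholding can leave a GRM very slightly
  indefinite.
* Boundary estimates ($\hat h^2 \in \{0, 1\}$) report missing SEs rather
  than fabricated ones; LRT = 0 reports a missing Wald SE and P = 1.
* Stepwise ties are broken by column order; the procedure is a fixed point
  iteration and terminates because each step strictly improves a finite
  criterion.
* Constant phenotypes, non-positive values for Box-Cox, cycles or duplicate
  IDs in pedigrees, all-SNPs-removed QC and infeasible pedigree targets all
  raise immediate, named errors.
* Missing ECG leads mark a record unphenotyped (mirroring exclusions for
  bundle branch block, atrial fibrillation or pacemakers) instead of
  aborting a cohort-level derivation.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
power and recovery simulations use 116–132-family panels (440–510
phenotyped members) with 120–200 replicates per condition, the GRM path
uses 2,000 SNPs on ~500 individuals, the oracle checks use 100 random
pedigrees of ≤ 40 members and dense evaluations at n ≤ 200, and the
attenuation property uses 50 independent cohorts. These sizes put every
Monte-Carlo bound well inside its noise floor while keeping a full run in
minutes on one CPU.

## Known limitations

* The family-structure mix fixes a Fisher-information ceiling: at ~427
  phenotyped members in 116 families of mean size 3.7, the sampling SE of
  ĥ² at $h^2 = 0.35$ cannot fall below ≈ 9.5 percentage points, whereas
  larger extended families (as in the motivating design, drawn from a panel
  averaging ~5.7 members) would reach ≈ 7.5. The power simulation reports
  what the simulated panel actually delivers.
* The heterogeneity test between modalities is the independent-estimates
  approximation $z = (h^2_a - h^2_b)/\sqrt{SE_a^2 + SE_b^2}$ and ignores
  the covariance induced by overlapping individuals; its output says so.
  A properly paired statistic requires the joint fit, which is out of
  scope.
* Single-kernel models only: no bivariate heritability, GxE, dominance, or
  association scanning; binary PLINK formats are not parsed (text PED/MAP
  and FAM only).
* The Wald-from-LRT SE degrades near $\hat h^2 = 0$ (LRT → 0); the
  information-based SEs are the ones used for interval coverage.
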