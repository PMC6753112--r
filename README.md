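# famh2 — family-based heritability of ECG and CMR ventricular phenotypes

Left-ventricular hypertrophy (LVH) is a strong risk factor for heart failure
and cardiovascular death, and its measures are heritable — but *how*
heritable depends on the measurement modality. ECG-based indices of
left-ventricular mass (LVM) tend to show much higher heritability than
anatomical mass measured by imaging, partly because surface ECG voltages are
confounded with highly heritable body-habitus traits such as chest size.
`famh2` implements the full analysis pipeline for quantifying this in
extended-family cohorts phenotyped by both 12-lead ECG and cardiovascular
magnetic resonance (CMR), for statistical geneticists and cardiovascular
epidemiologists who want to estimate and compare narrow-sense heritability
across modalities.

## The models

**Phenotype derivation.** ECG LVH indices from QRS amplitudes (mV):
Sokolow-Lyon voltage `SV1 + RV5`; Cornell voltage `RaVL + SV3` (+0.6 mV in
women); duration products (index × QRS duration, mV·ms); the 12-lead QRS
amplitude sum; and ECG LVM in grams from the sex-specific linear equations

    men:   0.026 (RaVL + SV3) + 1.25 weight + 34.4
    women: 0.020 (RaVL + SV3) + 1.12 weight + 36.2

CMR masses are tissue volume × 1.05 g/cm³ (myocardial specific density),
indexed to Du Bois body surface area; chest volume is the cylinder π r² h
with r half the lateral chest diameter.

**Covariate adjustment.** Blood pressure is pre-adjusted for
antihypertensive treatment (+15/+10 mmHg systolic/diastolic); each trait is
Box-Cox transformed at its profile-likelihood-optimal λ, residualized
against covariates chosen by forward-backward stepwise OLS at P < 0.01.

**Heritability.** Two variance-components models of the adjusted residuals
y with covariance

    V = σ²_g K + σ²_e I,      h² = σ²_g / (σ²_g + σ²_e)

where the kernel K is either twice the pedigree kinship matrix (2Φ, fitted
by maximum likelihood and tested against the σ²_g = 0 null by LRT, with the
Wald-approximation SE = h²/√LRT) or a SNP genetic relationship matrix with
off-diagonals below 0.05 set to zero — the IBS-thresholding that makes
SNP-based REML estimates approximate identity-by-descent estimates in
family data (fitted by REML, delta-method SEs, optional unconstrained
components). Both fits run on one eigendecomposition of K, so hundreds of
simulation replicates against a fixed panel cost O(n²) each.

**Comparisons.** Relative-pair (sibling / parent-child / avuncular)
correlations with double entry for symmetric classes, Fisher-z comparison
of correlations, a heterogeneity z-test between heritability estimates,
Spearman confounding checks, and a power simulation that measures the
sampling SE of ĥ² achievable on a given family panel.

**Synthetic cohorts.** Because family studies of this kind rarely deposit
raw data, the package ships a generator with known ground truth: 116
extended families (~427 phenotyped members) built from four structure
templates, gene-dropped genotypes, polygenic trait values with exact
2Φσ²_g covariance, and a covariate model in which chest lateral diameter
confounds ECG LVM (Spearman ρ ≈ 0.67) so that chest adjustment attenuates
its heritability — the phenomenon the analysis is designed to expose.

## Worked example

```r
library(famh2)

cfg <- run_config(
  simulate = list(ped_spec  = pedigree_spec(seed = 2026),
                  geno_spec = genotype_spec(n_snps = 2000),
                  model     = trait_model()),
  recipes = list(
    list(trait = "ecg_lvm",
         candidates = c("age", "sex", "height", "weight", "sbp_adj")),
    list(trait = "ecg_lvm", label = "ecg_lvm_chestadj",
         candidates = c("age", "sex", "height", "weight", "sbp_adj",
                        "chest_lateral_diameter")),
    list(trait = "cmr_lvm",
         candidates = c("age", "sex", "height", "weight", "sbp_adj")),
    list(trait = "rv_mass",
         candidates = c("age", "sex", "height", "weight", "sbp_adj"))),
  seed = 2026)

res <- run_pipeline(cfg)
print(res)
#>             trait n_phenotyped h2_pedigree se_pedigree p_pedigree n_genotyped
#>           ecg_lvm          440       0.481      0.0867   1.48e-08         440
#>  ecg_lvm_chestadj          440       0.218      0.0935   9.90e-03         440
#>           cmr_lvm          440       0.152      0.0940   5.30e-02         440
#>           rv_mass          440       0.422      0.0876   7.10e-07         440
#>  h2_grm se_grm    p_grm                        covariates
#>   0.464 0.0859 2.27e-08                 weight+height+sex
#>   0.222 0.0993 9.56e-03 weight+chest_lateral_diameter+sex
#>   0.160 0.1008 4.60e-02                        sex+weight
#>   0.445 0.0885 2.34e-07                        sex+weight
#>
#> chest/ECG-LVM Spearman rho = 0.610 (P = 2.96e-46)
```

Reading the table: ECG LVM looks strongly heritable (ĥ² ≈ 0.48 on both the
pedigree and the thresholded-GRM kernel), but adding chest lateral diameter
to the adjustment set drops the estimate to ≈ 0.22 — the voltage signal was
inheriting much of its familial resemblance from chest geometry. CMR
(anatomical) LVM is only modestly heritable (≈ 0.15, truth 0.20 in this
simulation), while right-ventricular mass recovers its generating value
(0.42 vs truth 0.44). The two kernels agree closely throughout, and the
Spearman ρ between chest diameter and ECG LVM reproduces the confounding
the generator encodes. `tidy()`, `glance()` and `autoplot()` methods are
available on fits, power results and pipeline runs.

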