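# pigbias — hair pigmentation bias in hair cortisol studies

Hair cortisol and cortisone concentrations (pg per mg of proximal scalp
hair, each cm integrating roughly one month of systemic exposure) are
popular chronic-stress biomarkers — but darker hair carries higher measured
concentrations. Is that a **local hair-shaft effect** of pigmentation, pure
**population stratification** (hair colour tracks ancestry, ancestry tracks
systemic hormone levels), or a marker of **minority stress**? The answer
decides whether hair-hormone studies in admixed populations are confounded
and how they should be adjusted.

`pigbias` implements the analysis pipeline that separates these
explanations, plus a synthetic admixed-cohort generator that realizes each
causal scenario so the pipeline's operating characteristics can be
demonstrated end to end:

* **Polygenic hair-colour score.** In a training split, hair colour
  (7 categories, treated continuously) is regressed jointly on candidate
  pigmentation SNP dosages plus 20 principal components of ancestry;
  candidates in strong LD are pruned by iterated variance-inflation-factor
  elimination (VIF = 1/(1−R²), threshold 10). SNPs with p < 0.05 define the
  score S = Σⱼ βⱼ·dosageⱼ (higher = genetically darker hair), standardized
  in the validation split.
* **Outcome models.** Hormones are Box-Cox transformed — λ maximizes the
  profile likelihood, including the Jacobian term (λ−1)Σlog y, over a
  covariate model; the order-reversing y^λ for λ<0 is multiplied by −1 —
  then standardized and regressed on the score with sex, age,
  corticosteroid use, and 20 standardized ancestry PCs (OLS, analytic SEs).
* **Pleiotropy screen.** Per-SNP hormone effects from ancestry-adjusted
  models are oriented to the darker-hair allele and pooled by
  inverse-variance weighting: Cochran's Q = Σwᵢ(βᵢ−β̂)², wᵢ = 1/SEᵢ²,
  I² both as max(0,(Q−df)/Q) and from REML τ², and the Egger funnel
  regression of β on SE with weights 1/SE².
* **Power.** Local Cohen's f² = (R²_full−R²_reduced)/(1−R²_full) with
  noncentral-F power, noncentrality f²(u+v+1), v = n − terms − 1.
* **Synthetic cohorts.** Balding–Nichols allele frequencies (FST 0.1
  background, 3× for pigmentation SNPs with a directional darkness shift
  outside the European population), Dirichlet cluster-plus-admixture
  ancestry, threshold-liability 7-category hair colour, lognormal hormones,
  and scenario switches (`null`, `local`, `stratification`, `stress`,
  `mixed`) controlling how the hormone depends on pigmentation genetics,
  ancestry, or minority status.

## Worked example

```r
library(pigbias)

cfg <- scenario_config("stratification", seed = 7)  # confounding, no local effect
res <- run_pipeline(cfg)
print(res)
```

```
Pipeline result
  training n = 1565, validation n = 1697, score SNPs = 12
  validation hair-colour adj R2 = 0.297 (0.78 levels darker per SD)
  cortisol: lambda = -0.03; score beta 0.219 (SE 0.024) unadjusted -> 0.019 (SE 0.032) with PCs
    pleiotropy: Q = 14.47 (p = 0.208), I2(tau) = 25.8%; power(f2=0.0002) = 9%
  cortisone: lambda = -0.03; score beta 0.309 (SE 0.023) unadjusted -> 0.033 (SE 0.030) with PCs
    pleiotropy: Q = 18.66 (p = 0.067), I2(tau) = 40.9%; power(f2=0.0007) = 19%
```

Reading it: the score explains ~30% of validation hair-colour variance (one
SD of score ≈ 0.8 hair-colour levels darker). Because this cohort was
simulated under *pure stratification*, the unadjusted score–cortisol
coefficient (0.219 SD per SD, apparently highly significant) collapses to
~0.02 once 20 ancestry PCs enter the model — the published attenuation
pattern — and the pleiotropy screen shows no significant excess
heterogeneity. Under a `"local"` scenario the adjusted coefficient instead
stays at its true value (default 0.08 SD).

The numbered drivers under `analysis/` run the same workflow as a narrative
sequence (simulate → QC/ancestry → train score → hormone models →
pleiotropy → multi-replicate scenario experiments), writing their tables
under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_qc_ancestry.R
# ... through 06_scenario_experiments.R
```

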