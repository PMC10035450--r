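# gipipe

RNA-based genomic instability and immunogenicity analysis for bulk breast
tumor expression profiles.

Breast cancers rarely show the canonical immunotherapy-response markers,
yet genomic instability — loss of TP53 function, homologous recombination
deficiency (HRD) — is expected to generate neoantigens and an adaptive
anti-tumor response, including in ER-positive tumors that marker panels
focused on triple-negative disease would miss. `gipipe` implements the
analysis chain that quantifies this on expression data:

* **Nearest-centroid classifiers** for TP53 functional status
  (Mut-like vs WT-like), HRD (HRD+ vs HRD−) and three global immune
  classes (Adaptive-Enriched, Innate-Enriched, Immune-Quiet). Trainable
  (`train_centroids`), serializable (`read_centroids` /
  `write_centroids`), with Spearman / Pearson / Euclidean metrics,
  deterministic tie-breaking and explicit per-sample missing-gene policy.
* **AGI composite**: any genomic instability = TP53 Mut-like OR HRD-high;
  NGI = neither; incomplete calls yield `indeterminate` (`call_agi`).
* **Immune scoring**: per-sample median expression of marker panels (10
  immune cell types, adaptive/innate/overall composites, 48 genes in the
  default panel), single-gene PD-L1 (*CD274*) and CD8 (*CD8A*) scores, and
  third-quartile dichotomization into Low/High (`compute_scores`,
  `overall_immune`, `dichotomize_q3`).
* **Association statistics**: Welch t tests (`welch_t`); relative
  frequency differences (RFD) from identity-link binomial GLMs, i.e.
  adjusted percentage-point differences in outcome frequency with Wald 95%
  CIs and first-class "DNC" (does not converge) records
  (`estimate_rfd`); differential immune-score linear models with
  Benjamini–Hochberg correction (`differential_scores`).
* **Recurrence analysis**: Kaplan–Meier curves, log-rank tests, and crude +
  adjusted Cox proportional-hazards models of immune class within AGI and
  NGI strata, with stage-IV exclusion, 5-year administrative censoring,
  Efron ties and a covariate × log(time) proportionality check (`km_fit`,
  `cox_fit`, `recurrence_analysis`).
* **Synthetic cohorts**: `generate_cohort(default_config())` draws cohorts
  with the calibrated statistical structure of the motivating study —
  ER-dependent TP53/HRD prevalence, AGI-dependent immune-class mixing,
  centroid-structured expression with Gaussian noise, and
  proportional-hazards recurrence whose class hazard ratios act only
  within the AGI stratum — so the whole pipeline is testable without any
  access-controlled download.
* **Orchestration**: `run_pipeline(pipeline_config(...))` runs
  simulate/load → classify → score → AGI → cross-tabs → RFDs →
  differential scores → survival from one config, writing tidy CSVs and a
  JSON manifest that accounts for every excluded sample.

The core model for associations is the linear-probability GLM
`P(Y = 1) = β₀ + β₁·exposure + γ·covariates` (binomial family, identity
link), whose exposure coefficient ×100 is the RFD in percentage points;
recurrence follows the Cox model `λ(t | x) = λ₀(t)·exp(xᵀβ)` with hazard
ratios `exp(β)` reported per immune class against the Adaptive-Enriched
referent.

## Worked example

```r
library(gipipe)

cfg    <- default_config(n_samples = 1200, seed = 7)
cohort <- generate_cohort(cfg)
#> synthetic_cohort: 1200 samples x 500 genes; AGI 727 / NGI 473

tp53 <- call_signature(cohort$expression, expected_centroids(cfg, "tp53"))
hrd  <- call_signature(cohort$expression, expected_centroids(cfg, "hrd"))
agi  <- call_agi(tp53$label, hrd$label)
table(agi)
#>           AGI           NGI indeterminate
#>           727           473             0
```

AGI tumors show elevated overall immune expression (median of the 48
marker genes), and a ~23 percentage-point higher frequency of the
adaptive-enriched immune class after age/race adjustment:

```r
oi <- overall_immune(cohort$expression, default_marker_panel())
welch_t(oi[agi == "AGI"], oi[agi == "NGI"])
#>      t       df        p
#> 5.2712 916.5340   <1e-6

imm <- call_signature(cohort$expression, expected_centroids(cfg, "immune"))
st  <- data.frame(cohort$annotations, agi = agi, immune_class = imm$label)
estimate_rfd(as.integer(st$immune_class == "Adaptive-Enriched"),
             factor(st$agi, levels = c("NGI", "AGI")),
             covariates = st[, c("age", "race")])
#>   level referent  rfd ci_low ci_high converged
#> 1   AGI      NGI 23.3   18.2    28.4      TRUE
```

Within the AGI stratum, recurrence differs across immune classes
(adaptive-enriched referent; adjusted for age, race, stage, ER), while the
generator leaves the NGI stratum class-neutral:

```r
rep <- recurrence_analysis(st)
rep$strata$AGI$cox_adjusted$table[, c("term", "hr", "ci_low", "ci_high", "p")]
#>                          term   hr ci_low ci_high        p
#> 1    immune_classImmune-Quiet 2.40   1.49    3.89 0.000356
#> 2 immune_classInnate-Enriched 2.02   1.27    3.20 0.002798
rep$strata$AGI$km$logrank
#>    chi2      df       p
#> 12.9886  2.0000  0.0015
```

The 1,200-sample cohort above yields an AGI stratum of ~700 tumors with
~120 recurrences, the scale of the motivating study; at that event count
the class effect is detectable but estimated with wide intervals, which is
why parameter-recovery checks use larger, event-rich cohorts.

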