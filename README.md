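# tilrep

Longitudinal T cell repertoire analysis around adoptive cell transfer
(ACT) of tumour-infiltrating lymphocytes (TILs).

When a patient receives an expanded TIL infusion after lymphodepleting
chemotherapy, the fate of the infused clones — engraftment, expansion,
persistence — is visible in targeted TCR-beta sequencing of serial blood
samples: PBMC genomic DNA, PBMC RNA, plasma cell-free DNA (cfDNA), and
the infusion product itself. `tilrep` takes the per-sample clonotype
tables produced by such an assay (MiXCR clone exports or AIRR
Rearrangement TSVs) and answers the analysis questions:

* How diverse is each repertoire, and how does diversity move over
  treatment? — Simpson λ = Σ(nᵢ/N)², inverse Simpson 1/λ, Shannon
  H = −Σ(nᵢ/N)ln(nᵢ/N), richness S, evenness H/ln S, clonality
  C = 1 − H/ln S, and the abundance held by large (1–5%) and
  hyperexpanded (>5%) clones.
* How similar are two repertoires? — Morisita–Horn overlap
  M = 2Σpᵢqᵢ / (Σpᵢ² + Σqᵢ²) on relative abundances, plus squared
  Pearson correlation of clonotype abundances across compartments.
* How much of the blood repertoire do TIL clonotypes occupy at each
  timepoint, and how persistent are they? — TIL abundance and
  persistence statistics against the infusion product and baseline.
* Which clones are *expanded*? — a data-driven split of each
  rank-abundance curve by a single (at-most-one-change) variance
  change point, replacing fixed thresholds like ">1% of the repertoire".
* Does presence in the baseline or the infusion product predict
  post-infusion expansion? — relative risk RR = (A/(A+B))/(C/(C+D))
  with SE(log RR) = √(B/(A(A+B)) + D/(C(C+D))) and 95% CI.
* Was each sample sequenced deeply enough? — richness-vs-depth
  subsampling curves, a penalized-spline (GAM) fit, and a
  first-derivative saturation decision.

A seeded synthetic cohort generator with known ground truth
(`cohort_config()` / `simulate_cohort()`) stands in for patient data, so
the entire pipeline is testable end to end. It emulates nine-patient
cohorts with five compartments per patient, skewed clone-size laws with
a planted expanded head, partial baseline↔product clonotype sharing,
responder effect sizes, multinomial sequencing noise, and
unproductive/singleton contamination.

## Worked example

Simulate a cohort, run the full analysis, and look at the response-group
summary:

```r
library(tilrep)

cfg <- cohort_config(seed = 1)          # 9 patients, 3 responders
sim <- simulate_cohort(cfg, "cohort")   # writes AIRR TSVs + manifest.tsv
run_pipeline(file.path("cohort", "manifest.tsv"),
             default_config(), "analysis")

readr::read_csv(file.path("analysis", "cohort_summary.csv"))
```

```
   statistic                      group             n median    min    max
 1 baseline_til_abundance         non_responder     6 0.0462 0.0349 0.0754
 2 baseline_til_abundance         responder         3 0.443  0.394  0.554
 3 first_post_til_abundance       non_responder     6 0.257  0.252  0.261
 4 first_post_til_abundance       responder         3 0.531  0.526  0.547
 ...
18 rr_til_product                 responder         3 10.2   9.58   15.1
```

Reading this: simulated responders carry ~44% of their baseline
repertoire in infusion-product clonotypes against ~5% for
non-responders; product clones take ~53% vs ~26% of the first
post-infusion repertoire; and presence in the TIL product multiplies a
clonotype's risk of post-infusion expansion by ~10 in responders — the
planted effect directions, recovered by the measurement pipeline from
the noisy sequenced tables. The same
directory holds per-sample diversity (`diversity.csv`), the all-pairs
Morisita matrix (`overlap_matrix.csv`), longitudinal tracking tables
(`tracking.csv`), change-point thresholds (`expansion.csv`),
relative-risk tables (`risk.csv`), saturation QC (`saturation.csv`), a
quarantine list with reason codes, and a JSON run log of every setting
used.

Single-sample statistics work on any AIRR/MiXCR table:

```r
s <- read_clonotype_table("sample.tsv", format = "airr")
f <- filter_repertoire(s)         # TRB, drop unproductive, drop singletons
diversity_profile(f$sample)
classify_expanded(f$sample)       # expanded/background change point
```

A thin CLI wrapper is installed at `inst/cli/tilrep.R`
(`Rscript tilrep.R simulate|run|stats ...`).

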