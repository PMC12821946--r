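---
title: "Methods: tracking TIL clonotypes through peripheral T cell repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking TIL clonotypes through peripheral T cell repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilrep)
```

## The analysis problem

Adoptive cell transfer (ACT) of tumour-infiltrating lymphocytes (TILs)
infuses an ex vivo expanded T cell product into a lymphodepleted patient.
Whether the infused clones engraft, expand and persist in peripheral blood
is measurable with targeted TCR-beta sequencing of serial samples: PBMC
genomic DNA, PBMC RNA, plasma cell-free DNA (cfDNA), and the infusion
product itself. `tilrep` implements the downstream half of that workflow.
It consumes per-sample clonotype tables (MiXCR clone exports or AIRR
Rearrangement TSVs), and produces per-sample diversity statistics,
pairwise repertoire overlap, longitudinal TIL tracking, a data-driven
expanded/background partition of each repertoire, and a relative-risk
analysis of post-infusion clonal expansion.

Everything downstream of the clonotype table is in scope; read alignment
and clonotype assembly are not. The package never sees FASTQ files.

## Clonotype identity

A clonotype is keyed, by default, on the tuple (CDR3 nucleotide sequence,
V gene, J gene) with allele designations stripped, so `TRBV7-2*01` and
`TRBV7-2*02` match. Amino-acid-level matching (`aa_vj`) and bare-CDR3
matching (`nt`) are available through every reading function because
platforms disagree about how much context defines a clone; the choice is
recorded in each sample object and must be consistent across samples that
are compared. Cross-compartment matching (DNA vs RNA vs cfDNA) uses the
nucleotide key by default — the most conservative choice, since identical
nucleotide rearrangements in two compartments are almost surely the same
clone, while amino-acid convergence is common.

## Filtering

Repertoires are restricted to the TCR-beta locus, then unproductive
clonotypes are removed, then singletons (count 1). Unproductive means the
`productive` flag where the table carries one, otherwise a stop (`*`) or
frameshift (`_`) symbol in the CDR3 amino-acid sequence; a productive flag
contradicted by a stop/frameshift symbol is demoted. The order is fixed —
unproductive first, singleton status judged on what remains — so the
`FilterReport` step counts are deterministic and always sum to the
richness change. Both the clonotype-level and the read-level unproductive
fraction are reported, since contamination rates are usually quoted per
clonotype but matter per read.

## Diversity statistics

For clone counts $n_i$, total $N$, richness $S$:

$$\lambda = \sum_i (n_i/N)^2, \qquad
  H = -\sum_i (n_i/N)\ln(n_i/N), \qquad
  SEI = H/\ln S, \qquad C = 1 - SEI$$

with inverse Simpson $1/\lambda$ as the headline diversity number.
Natural logarithms are used throughout and there is deliberately no
log-base option: silently mixing bases makes Shannon values
incomparable between runs. For $S = 1$ the evenness is defined as 0 and
clonality as 1, the limit of a repertoire collapsing onto one clone.

Size classes are abundance-weighted and half-open: *large* clones occupy
$(1\%, 5\%]$ of the repertoire, *hyperexpanded* clones $(5\%, 100\%]$, so
the two classes partition everything above 1% and a clone sitting exactly
at 1% belongs to neither. A clonotype-count variant is available behind
the `weighted` flag.

## Overlap and cross-compartment correlation

Repertoire similarity uses the Morisita–Horn index on relative abundances
$p_i = x_i/X$, $q_i = y_i/Y$ over the union of keys:

$$M = \frac{2\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}$$

This form is exactly 1 for proportionally identical repertoires (so the
self-diagonal of an all-pairs heatmap is 1), 0 for disjoint ones, and
invariant to multiplying either sample's counts by a constant. A
"literal" variant dividing $2\sum x_i y_i$ by $(S_x + S_y)XY$ with $S$
the richness is retained for auditability, but it does not normalise
self-overlap to 1 and is not used by the pipeline. Per-patient mean
overlap is averaged over distinct unordered pairs within one compartment;
self-pairs and cross-compartment pairs are excluded.

Cross-compartment abundance agreement is the squared Pearson correlation
of relative abundances, by default over the intersection of keys on the
linear scale — the minimal reading of a scatter plot of shared-clone
abundances. Union scope (zeros for absent clones) and log10 transform are
options recorded in the output; log mode excludes union zeros. Fewer than
three usable points yields `NA`, never an error, because sparse cfDNA
repertoires routinely share only a handful of clones with PBMC DNA.

## TIL tracking

The TIL clonotype set is the key set of the DNA infusion product
(`product_only`), optionally intersected with the union of all PBMC
samples (`product_and_pbmc`) — the stricter set is always a subset. TIL
abundance of a sample is the summed relative abundance of TIL clonotypes
in it. Persistence of a reference in a post-infusion sample comes in two
modes: `abundance` (share of the post repertoire held by reference
clones — the classical persistence statistic) and `clonotype_fraction`
(share of post clonotypes, optionally restricted to a label set such as
the expanded clones, that are present in the reference).

"Baseline" is the sample with the largest non-positive day relative to
infusion; "first post-infusion" the smallest strictly positive day.
Tracking tables zero-fill every clonotype ever seen in a patient's series
so that stacked-bar rendering and timepoint differencing are unambiguous.

## Expanded/background partition by variance change point

Rank-abundance curves of T cell repertoires drop sharply between a small
expanded head — clones under antigen-driven expansion, with large
between-clone size variation — and a long background tail of clones at
similar small sizes. Instead of an arbitrary fixed cutoff (e.g. ">1% of
the repertoire"), the package finds the drop with a single (at most one
change) change-point search on the curve: each candidate split $\tau$ is
scored by the Gaussian segment cost $m\,\ln\hat\sigma^2_{MLE}$ with
segment-specific mean and variance, and the best split is accepted when
the twice-log-likelihood gain over the unsplit model exceeds a penalty
(BIC, $3\ln n$, by default; a manual penalty is available and the value
used is recorded in every result).

Numerical choices that matter:

* **Variance floor.** Clone counts are integers, so rank-abundance tails
  contain long runs of exactly tied values whose MLE variance is zero; an
  absolute floor near zero would make any split isolating such a run look
  infinitely good and drag $\tau$ deep into the tail. Segment variances
  are therefore floored at $10^{-4}$ of the full-sequence variance. The
  relative floor keeps constant segments finite without rewarding them
  and makes the search exactly invariant to rescaling all counts.
* **Nuisance mean.** The segment mean obviously shifts along with the
  variance on these curves, so each segment estimates its own mean; a
  global-mean, variance-only variant would conflate the two changes.
* **Ties** between equal-cost splits go to the smallest $\tau$ — the
  fewest expanded clones, the conservative call.
* **Transform.** The search runs on raw counts by default; a log
  transform is available (counts span decades) and is recorded in the
  result.
* A constant sequence, or one shorter than $2 \times$ `min_segment`
  (default 2, the least that defines a variance), returns a no-change
  result with a reason code.

The search is exhaustive over all admissible $\tau$, so a brute-force
re-derivation must agree exactly; the test suite enforces this on random
sequences.

## Relative risk of post-infusion expansion

For the first post-infusion PBMC DNA repertoire, its clonotypes are
cross-classified by (expanded vs background) × (present vs absent in a
reference sample — the PBMC DNA baseline or the DNA infusion product):

$$RR = \frac{A/(A+B)}{C/(C+D)}, \qquad
  SE(\log RR) = \sqrt{\frac{B}{A(A+B)} + \frac{D}{C(C+D)}}$$

with the 95% CI $\exp(\ln RR \pm 1.96\,SE)$ and the decision flag set by
whether the CI excludes 1. The clonotype universe is the target sample's
post-filter clonotypes only, because the event is defined on that
sample's partition. Zero cells in $A$ or $C$ return a sentinel carrying
the raw table by default; the Haldane–Anscombe +0.5 correction is opt-in
and flagged in the output, so corrected values are never silent.

## Saturation QC

Sequencing depth adequacy is judged from a richness-versus-depth curve:
the clonotype table is subsampled without replacement (multivariate
hypergeometric on clone counts — the clone-table-level equivalent of
read subsampling) to 10%…95% of the observed depth in 5% steps plus the
full sample, with 5 replicates per level by default to give the smoother
a variance estimate. A penalized cubic spline (a GAM with smoothing by
GCV) is fitted and the first derivative at the deepest level is estimated
from the basis, with a 95% CI from the coefficient covariance. The sample
is *saturated* when the upper CI bound of that derivative is at most
`epsilon`, one new clonotype per 10,000 reads by default. The decision
rule and epsilon are stated in the output so they can be audited; the
module reports, it never waives thresholds for borderline samples.

## The synthetic cohort generator

Because the patient-level data behind this kind of study are external,
every pipeline stage is validated against a seeded generator with known
ground truth. One simulated patient comprises baseline PBMC DNA/RNA and
cfDNA, a DNA+RNA infusion product, and serial post-infusion draws
(days 28 and 98 by default; baseline day −14, product day 0).

* **Clone sizes** follow a Zipf law with exponent 0.45 whose top 15 ranks
  are boosted ×3, planting a distinct expanded regime. These values were
  calibrated against the magnitudes this assay reports for genomic DNA
  repertoires — inverse Simpson on the order of 10²–10³, clonality
  0.05–0.2, an expanded head holding roughly 30–50% of reads — rather
  than to a steeper textbook exponent, which at this richness would put
  >90% of all reads into the head and make every repertoire look almost
  monoclonal. A lognormal alternative is available for robustness tests.
* **Sharing.** The infusion product shares a fraction θ (default 0.05) of
  baseline clonotypes, chosen uniformly, so the expected baseline TIL
  abundance equals θ. Within the shared set, product frequencies track
  baseline ranking — the product over-represents the patient's own
  expanded clones.
* **Post-infusion mixing.** The post repertoire draws a fraction w
  (default 0.25, waning ×0.7 per later timepoint) from product
  frequencies and 1−w from an endogenous compartment: surviving baseline
  clones (10% of baseline keys, frequencies preserved) plus novel influx.
  Influx defaults to 0.8 of the endogenous mass: reconstitution after
  lymphodepletion is mostly de novo, which keeps baseline↔post abundance
  overlap low in the absence of product sharing, matching the very low
  between-timepoint overlap this assay reports for non-responders. Novel
  clones are uniform-sized — naive-like background with no antigen-driven
  size variation — so the post-infusion expanded head is carried by
  product and surviving baseline clones, not by the de novo compartment.
* **Responder effects** multiply θ (×8), w (×2) and the clone-size
  exponent (×1.5), reproducing the direction and rough size of the
  response-associated contrasts (baseline TIL abundance a few percent vs
  tens of percent; post-infusion TIL abundance roughly doubling).
* **Compartments.** cfDNA is a sparse (6% of DNA richness), skewed
  (frequencies raised to the 1.5 power) resampling of the DNA
  frequencies; RNA multiplies DNA frequencies by per-clone lognormal
  expression factors (sdlog 0.5). Reads are multinomial at
  compartment-specific depths (2.5M gDNA, 170k cDNA, 1M cfDNA).
* **Contamination.** Unproductive clonotypes are injected at a 22.1%
  clonotype rate — half with frameshift `_`, half with stop `*` symbols,
  so both detection rules are exercised — plus 15% singleton inflation.
  The default filters remove all of it.
* **Seeds.** Every draw is keyed by (master seed, patient, sample,
  purpose), so adding a patient never perturbs existing ones and the same
  master seed reproduces a cohort byte for byte.

What the generator does *not* emulate: sequence-realistic V(D)J
recombination (CDR3 strings are random), PCR amplification bias,
cross-sample contamination, clock-time clonal kinetics between draws, or
antigen specificity. Passing tests therefore demonstrate that the
statistics and their implementations behave correctly on data with the
right structure and magnitudes — not that the biological conclusions of
any particular cohort would replicate.

## Problem sizes and runtime

The validation suite uses 600-clonotype baselines, 300-clonotype
products, and full per-compartment depths; Monte-Carlo checks use 50
cohorts (9 patients each), 500 planted change-point sequences, 1,000
random repertoires/pairs for the closed-form oracles, and 10,000
simulated contingency tables for CI coverage. These sizes keep every
oracle comparison exact while the whole suite runs in minutes on one
core.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 1)
sim <- simulate_cohort(cfg, "cohort_dir")
run_pipeline(file.path("cohort_dir", "manifest.tsv"),
             default_config(), "analysis_dir")
readr::read_csv(file.path("analysis_dir", "cohort_summary.csv"))
```

## Known limitations

* The change-point model assumes a single expanded/background break; a
  repertoire with several abundance regimes gets one conservative split.
* Saturation CIs come from the smoother's coefficient covariance and
  inherit its assumptions; with a single subsampling replicate per level
  the residual variance is under-informed.
* The relative-risk CI is the standard log-normal approximation; it is
  anti-conservative for very small cells, which is why zero cells
  produce sentinels rather than numbers unless a correction is demanded.
* Group summaries are descriptive (median and range) by design; with
  3 vs 6 patients, hypothesis tests would be theatre.
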