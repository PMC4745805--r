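---
title: "Label-free proteomics biomarker discovery: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free proteomics biomarker discovery: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomarker)
```

## The analysis problem

Label-free bottom-up proteomics of body-fluid vesicles (for example urinary
exosomes) yields, per sample, a list of identified peptides with precursor
intensities and spectrum counts. A biomarker-discovery study compares a
patient group against healthy controls and asks two questions per protein:
*is it differentially abundant*, and *how well does it separate the groups
as a diagnostic test*. `exomarker` implements that workflow for a
case-control design with technical replicates, together with a synthetic
cohort generator carrying known ground truth, so that every stage can be
validated without access to any real (and typically unreleased) per-sample
quantification.

## Quantification model

Three protein-level channels are derived from peptide evidence:

* **PSM (spectral counts)** — the summed spectrum counts of a protein's
  peptides in a run; a discrete, semi-quantitative abundance proxy.
* **Top3TIC** — the mean of the three most intense peptide precursor
  signals. The mean (not the sum) is used so proteins with one or two
  observed peptides stay on the same scale; `top3_tic()` exposes the
  aggregator for callers preferring the summed dialect. When duplicate rows
  exist for one peptide in one run (charge states), intensity is collapsed
  by maximum and spectra by sum before ranking.
* **iBAQ** — summed peptide intensity divided by the number of
  *theoretically observable* tryptic peptides, putting proteins of
  different length on an approximately molar scale. Observability is
  defined as a fully cleaved (0 missed cleavages) peptide of 7–30 residues;
  both bounds are conventions of common search-engine dialects and are
  configurable in `digest_config()`.

In-silico digestion cleaves C-terminal of K/R, by default *without* the
proline restriction (cleavage before P allowed), with up to 2 missed
cleavages — matching the identification settings such experiments typically
use. Non-canonical residues are rejected with their position; modified
peptides are an identification-level concern and out of scope here.

Technical replicate runs are collapsed to samples by the mean, and a
protein counts as detected in a sample when detected in at least one run.
Zero is the only missing-value code: a value of exactly 0 means "below the
detection limit", which downstream presence/absence tests rely on.

## Differential testing

Per protein, three complementary tests are run:

1. **Presence/absence** — Fisher's exact test on the 2×2 table of
   detected/absent counts per group, two-sided by the probability-ordering
   rule (every table with the observed margins whose hypergeometric
   probability does not exceed the observed one contributes to *p*). Other
   two-sided conventions exist (doubling the one-sided *p*); the
   probability ordering is the commonest and is what reference
   implementations use.
2. **Label-free abundance** — a heteroscedastic (Welch) two-sided t-test on
   each of the PSM and Top3TIC channels; a protein is `lfq_significant`
   only when *both* channels give *p* < α (strictly), with α = 0.05 and no
   multiple-testing correction, matching the discovery-style procedure this
   package reproduces. Benjamini–Hochberg columns are emitted for modern
   reuse but gate nothing.
3. **Pooled iBAQ validation** — each group's samples pooled into three
   sets, all six pools normalized to the mean patient-pool total, the
   ratio of pool means reported with a two-sided t-test on the triplicates.
   A protein present in exactly 1 of a group's 3 pools is *invalid*
   (irreproducible); a protein absent from all control pools but present in
   ≥2 patient pools is *patient-unique* with ratio `Inf` and remains valid.

Non-detected values enter the t-tests as zeros by default: under
detection-limit censoring, absence is informative, and excluding zeros
would compare only the detected tails. `zeros = "exclude"` switches to
exclusion for users who prefer it.

The master `significantly_altered` flag requires the dual-channel rule
*and* a valid, significant iBAQ change — the criterion later used by the
focus list.

## Marker evaluation

* **Full-specificity threshold** — the maximum control value, with
  positivity strictly above it. This makes "every control negative"
  literally true; when a protein is absent from all controls the threshold
  is 0 and positivity is detection itself.
* **Sensitivity** — fraction of patients above the threshold, displayed as
  a percent rounded half away from zero (10/16 = 62.5% prints 63%,
  11/16 = 68.75% prints 69%); base R's banker's rounding would print 62%
  and 69%, so `round_half_up()` exists as an explicit reporting helper.
* **Youden's J** — J = sensitivity + specificity − 1 maximized over
  midpoints between adjacent distinct pooled values plus ±∞ sentinels, ties
  broken toward the higher threshold (preferring specificity).
* **ROC/AUC** — the empirical staircase over all observed thresholds with
  trapezoidal area. Ties between a control and a patient value contribute
  ½, so the AUC equals the Mann–Whitney statistic divided by the number of
  pairs; no interpolation beyond trapezoids is performed.
* **Panels** — two clearly-labelled package conventions, because published
  reports of combined markers rarely state the combination rule: the
  OR-rule (`combine_markers_or_rule()`; positive on any member at its own
  threshold — specificity stays 1 on the defining controls, sensitivity can
  only grow) and a rank-based score (`combined_rank_score_auc()`; mean of
  within-cohort empirical quantiles, then AUC). Published descriptions of
  combined-marker ROC analyses are sometimes internally inconsistent about
  which pair was combined; this package treats the member set as a free
  argument rather than guessing.

The **focus list** keeps proteins that (i) are significantly altered by
both label-free channels and by validated iBAQ, (ii) reach ≥50% sensitivity
at the full-specificity threshold, and (iii) change ≥1.75-fold in either
direction (a ratio of 0.48 is a 2.08-fold effect). Both boundaries are
inclusive: published candidate tables contain printed ratios of exactly
1.75, which only an inclusive reading retains. `exclusion_filter()` then
removes candidates confounded by sampling conditions (e.g. proteins that
also differ between first and second morning urine voids).

## The synthetic cohort generator

`generate_cohort()` simulates, from one seed, everything downstream of
peptide identification — no spectra, retention times or m/z.

| Parameter | Default | Why |
|---|---|---|
| `n_control` / `n_patient` | 15 / 16 | the emulated study design |
| `n_proteins` | 1600 | discovery-scale urinary-exosome proteome |
| `n_up` / `n_down` | 221 / 25 | planted regulation counts |
| `fold_change_range` | 1.75–20, log-uniform | from the focus-criterion floor to strong enrichment |
| `base_sdlog` | 1.8 (natural log) | ≥4 orders of magnitude dynamic range; top protein ≈5% of total |
| `biological_sdlog` | 0.4 | ~50% between-subject CV, typical for body-fluid proteomics |
| `replicate_noise_sd` | 0.5 | calibrated so triplicate log-intensity Pearson r ≈ 0.87 |
| `target_detected` | 1150 of 1600 | sets the detection limit; per-sample detected counts land within ±20% |
| `triplicated_samples` | 6 per group | triplicates for a subset, single runs for the rest |
| `planted_quantiles` | 0.25–0.90 | markers must be detectable to be discoverable; plausible candidates are low-ppm, not the dominant structural proteins |

Peptide-level generation: each protein gets its digest's observable
peptides (capped at the 12 most ionizable), fixed log-normal ionization
factors, and per-run intensities equal to protein abundance × factor ×
residual noise; spectrum counts are Poisson in the log relative intensity.
Because iBAQ divides by the *full* observable count while evidence carries
at most 12 peptides, absolute iBAQ values are shrunk by a fixed per-protein
factor — which cancels in every ratio the pipeline reports.

**Compositionality.** Equal protein amounts are measured per sample, as in
real label-free workflows, so each simulated sample is rescaled to a
common loading total after effects are planted: the data are relative.
Planting net up-regulation (221 up at a mean ~7-fold) therefore shrinks
*every* measurable patient:control ratio by a common composition factor
(~0.7 at defaults) — nulls sit slightly below 1 and the ratio distribution
skews, exactly the behaviour real compositional cohorts show. The truth
table records both the biological `fold_change` and the measurable
`relative_fold_change` (biological × composition factor); recovery is
assessed against the latter, because the absolute fold change is not
identifiable from equal-loading data. At default noise the median relative
error of pooled-iBAQ ratio estimates over uncensored planted proteins is
about 15%.

Hard censoring at the detection limit, applied after planting, produces
presence/absence group differences naturally: an up-regulated protein near
the limit is detected in patients and absent from controls, reproducing
the detected-in-0-of-15-controls marker pattern.

What the generator does **not** emulate: peptide-level missingness
independent of protein abundance, shared peptides between proteins,
modifications, batch/run-order drift, and any real biological covariance
between proteins. Passing recovery tests therefore shows the pipeline is
correct and calibrated under the stated model — not that real cohorts of
this size would yield comparable candidate lists.

## Numerical choices

* Strict inequalities throughout positivity (`value > threshold`) and
  significance (`p < alpha`); the full-specificity threshold is the
  *smallest* threshold with specificity 1.
* Fisher extremeness uses a 1e-7 relative tolerance when comparing table
  probabilities, absorbing floating-point ties in symmetric tables.
* Welch degenerate cases: both groups constant and equal → *p* = 1; both
  constant and different → *p* = 0 (separation without sampling noise).
* Fold-change conventions under censoring: control mean 0 with patient
  mean > 0 → ratio `Inf` ("patient-unique"); both 0 → ratio 1.
* Youden ties break toward the higher threshold; ROC uses observed values
  plus ±∞ sentinels only.
* Display rounding (half away from zero, integers) happens only in
  reporting columns; all internal values keep full precision.

## Problem sizes used by the test suite

The package's own validation runs at sizes chosen to exercise every code
path at interactive speed: the default 1600-protein cohort for recovery
checks, 20 null cohorts of 200 proteins for calibration, exhaustive
Fisher-oracle comparison over all 2×2 tables with margins ≤ 20, and
randomized oracle checks (digestion, Welch, AUC, Youden) at small n. These
sizes are validation choices, not limits of the implementation.

## Known limitations

* No moderated/shrinkage statistics (limma-style) and no FDR gating: the
  reproduced procedure uses raw p-values, which a modern study should not.
* The 3-vs-3 pooled iBAQ t-test has little power; its role is validation
  of direction and magnitude, not discovery.
* Marker thresholds are in-sample: sensitivity at a threshold chosen on
  the same controls is optimistically biased, and no cross-validation or
  held-out cohort evaluation is provided (deliberately out of scope).
* Overlap utilities treat accessions as opaque strings; no UniProt parsing
  or isoform handling.
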