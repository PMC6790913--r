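---
title: "Consistency-based differential abundance for paired knockdown proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency-based differential abundance for paired knockdown proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(consistentprot)
```

## The problem

Label-free proteomics of paired perturbation experiments — here, siRNA
knockdown of filaggrin (*FLG*) in organotypic skin cultures versus matched
non-targeting (NT) controls from the same donor — produces thousands of
protein-group intensities per run, with strong donor-to-donor
heterogeneity and abundance-dependent missingness. With four donors, a
conventional significance threshold after multiple-testing correction
across >8000 proteins has little power and invites arbitrary cutoffs.
The approach implemented here instead asks for *consistency of direction
and magnitude across donors*: a protein is called down-regulated when the
knockdown/control ratio shows a reduction in every donor with evidence,
is at most 0.5 in at least three of four donors, and the protein is
reduced to undetectable levels in at most two donors; up-regulation is
the symmetric rule with a ratio of at least 1.2. Unadjusted paired
t-tests on log10 data accompany the calls for volcano visualisation but
play no part in classification.

## Pipeline

`run_pipeline()` chains the steps in the order they must occur:

1. **Decoy/contaminant removal** (`filter_contaminants_decoys()`):
   reversed-sequence database matches (the search's false-discovery
   control) and lab-originating contaminants are dropped. A row flagged
   as both is counted once, under reverse. Keratin rows *without* the
   contaminant flag are kept — epidermal keratins are genuine skin
   proteins.
2. **Blank-run keratin subtraction** (`subtract_keratin_blank()`):
   ambient keratin background estimated from instrument blank runs is
   subtracted from keratin-flagged rows, flooring at zero. This happens
   *before* normalization: background keratin mass would otherwise
   inflate sample totals and distort the scale factors. One blank value
   per protein is applied to every sample; a per-sample blank table can
   be passed instead by calling the function per sample subset.
3. **Total-abundance normalization** (`normalize_total()`): every
   sample is scaled to the lowest per-sample total intensity ("adjustment
   to the lowest total protein yield"), so all scale factors are ≤ 1.
   iBAQ values are scaled by the same per-sample factor, keeping the two
   quantitations mutually consistent. Within-sample ratios are exactly
   preserved, which is what makes every downstream KD/NT ratio invariant
   to global intensity rescaling.
4. **QC** (`replicate_correlation()`, `intensity_histogram()`):
   technical reproducibility as pairwise Pearson correlation of log2
   iBAQ over proteins detected in both members of a pair. Complete-case
   is deliberate: an intensity of 0 encodes "not detected", not "zero
   abundance", and correlating imputed zeros would overstate agreement.
5. **Differential calls** (`differential_calls()`): technical runs are
   aggregated per (protein, donor, condition) as the arithmetic mean over
   runs in which the protein was detected (0 if none); per-donor KD/NT
   ratios are formed where both sides are detected; the consistency rule
   classifies each protein as DOWN, UP, NS, or INELIGIBLE (detected in
   fewer than three donors).
6. **Enrichment** (`ora()`): hypergeometric over-representation of the
   DOWN and UP gene lists against user-supplied GMT gene sets, with the
   *quantified post-filter proteome* as the universe — enrichment against
   a whole-genome universe would mistake detectability for biology.
   Benjamini–Hochberg adjustment across all tested sets.

## Reading the rule precisely

Per donor, a protein is in one of four evidence states: a defined ratio
(detected in both conditions); KD-undetectable (detected only in NT — a
reduction to below the detection limit); NT-undetectable (detected only
in KD — an apparent appearance); or absent from both.

* DOWN requires no increase-direction evidence anywhere (every defined
  ratio < 1, no KD-only donor), at least three qualifying reductions
  (defined ratio ≤ 0.5, or KD-undetectable), and at most two
  KD-undetectable donors.
* UP requires no reduction-direction evidence (every defined ratio > 1,
  no NT-only donor) and at least three defined ratios ≥ 1.2. An
  NT-undetectable donor never counts toward qualification: a protein
  absent from every control is INELIGIBLE rather than infinitely
  up-regulated.
* A ratio of exactly 1 is neither a reduction nor an increase and
  blocks both calls, which (with down threshold < 1 < up threshold)
  makes DOWN and UP mutually exclusive by construction.

Ratios use normalized raw intensity, not iBAQ: iBAQ rescales by peptide
count, which cancels in a within-protein ratio but adds noise through
the integer count; it is kept for QC and abundance-distribution plots.

## The synthetic study

`generate_dataset()` emulates the study design so every stage is
testable without the deposited raw data: 4 donors × {KD, NT} ×
quadruplicate runs, 9000 genuine proteins plus 10 keratin contaminants
and 100 reversed decoys. Log2 intensity of protein *p* in sample
(*d*, *c*, *t*) is

$$\mu_p + \delta_{p,d} + \beta_p\,[c = \mathrm{KD}] + \varepsilon,$$

with baseline means $\mu_p \sim U(20, 30)$ (log2 of typical MS1
intensities), per-(protein, donor) biological effects $\delta_{p,d} \sim
N(0, 0.5)$, technical noise $\varepsilon \sim N(0, 0.25)$, and planted
effects $\beta_p = -2$ for a random 5% (DOWN truth), $+0.5$ for 5% (UP
truth — deliberately near the 1.2 threshold), 0 otherwise. Cells below
the detection limit — by default the 2nd percentile of the baseline
means — are censored to 0, reproducing the left-censored missingness of
real data. Decoys follow the same null model so FDR removal is
exercised non-trivially; contaminant keratins get flat,
condition-independent means, as instrument background would.

Three modelling choices deserve a note:

* The donor effect is drawn per (protein, donor), not per donor: a
  donor-level scalar shift is exactly removed by total-abundance
  normalization, so it would exercise nothing. Either way the effect
  cancels inside a within-donor KD/NT ratio, as in the paired design.
* Ten genuine (non-contaminant) keratins are planted among the null
  proteins. Without them every keratin row would carry the contaminant
  flag and be removed before blank subtraction ever ran, leaving that
  step untested; genuine epidermal keratins are precisely what blank
  subtraction exists for.
* What the generator does **not** emulate: peptide-level sampling,
  batch effects beyond donor, intensity-dependent variance, or
  correlated protein modules. Passing recovery tests on this model
  therefore demonstrates the pipeline's correctness under its stated
  assumptions, not its performance on any particular real dataset.

A consequence worth understanding: with a −2 log2 effect against a
detection limit at the 2nd percentile of a 10-unit-wide baseline range,
roughly a fifth of planted-DOWN proteins fall below the limit in the
knockdown in three or four donors. The consistency rule *by design*
refuses to call these (the "undetectable in a maximum of two
replicates" cap), so DOWN sensitivity on the default synthetic study is
about 0.80–0.84 rather than near 1 — remove the detection limit and it
is 1.00. This is an honest blind spot of the published rule for
complete knockouts, not a defect of the implementation; the
strongest-responding proteins are the ones the cap can exclude.

## Small-assay statistics

* `qpcr_summary()` / `ddct_fold_change()`: the 2^−ΔΔCt method with a
  reference gene; per-replicate folds are computed first and then
  averaged (set `average = "ddct"` for the geometric alternative).
* `thickness_summary()`: histology sections measured at three points
  (right, middle, left), averaged per section; KD/NT ratios per
  replicate and layer; mean ± SEM (sample sd/√n) across replicates with
  a paired t-test. The synthetic fixture plants a stratum-corneum ratio
  of 0.83 with between-replicate SD 0.16 over 10 replicates, so the SEM
  is about 0.05 — the magnitude of thinning reported for filaggrin
  knockdown epidermis.
* `condition_ratio()`: per-replicate KD/NT ratios (e.g. ceramide
  pmol/mg) with a t-based 95% interval, on the plain or log2 scale.

## Numerical choices and degenerate inputs

* Hypergeometric tail probabilities are summed in log space from
  `lchoose` terms with a max-shift, exact to enumeration for small
  universes and stable deep into the tail at proteome scale.
* `paired_t_log10()` flags zero-variance differences (within floating
  point) instead of reporting a meaningless t; fewer than two usable
  pairs gives `NA` with an `insufficient_pairs` flag.
* iBAQ with zero theoretical peptides is `NaN` with a warning, never 0.
* A sample with zero total intensity is a hard error at normalization —
  proceeding would silently divide by zero.
* Ties in enrichment ranking are broken by set name so output order is
  deterministic; all result TSVs are byte-stable under a fixed seed.

## Problem sizes used in the test suite

Unit and property tests run on compact studies (hundreds of proteins,
the full 4 × 2 × 4 design) where every invariant is checked exhaustively
or across dozens of random cases; the classifier is verified against an
independently coded brute force over the full 9^4 grid of ratio
patterns; parameter-recovery checks use the full 9000-protein default
study once. These sizes were chosen so the whole suite exercises every
stage at full design fidelity while remaining quick to run routinely.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 7)
ds <- generate_dataset(cfg)
res <- run_pipeline(ds$table, ds$design,
                    blank = generate_blank_run(cfg, ds$table),
                    gene_sets = generate_gene_sets(ds, seed = 8),
                    out_dir = "results")
table(res$calls$class)
res$enrichment$DOWN[1:3, 1:6]
```

## Limitations

* The rule's thresholds (0.5, 1.2, 3-of-4, cap of 2) are the published
  convention, exposed via `diff_config()` but not re-derived; they were
  chosen to give roughly balanced UP/DOWN lists, not calibrated error
  rates.
* No imputation and no moderated variance estimation are provided, by
  design — the method's point is to avoid distributional assumptions on
  missingness.
* ORA treats gene sets as flat; hierarchy-aware pathway statistics and
  network enrichment are out of scope.
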