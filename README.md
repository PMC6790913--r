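# consistentprot

Consistency-based differential abundance analysis for paired
knockdown-versus-control label-free proteomics, built for the design used
in siRNA knockdown studies of organotypic skin: a few donors, each
contributing a matched knockdown (KD) and non-targeting-control (NT)
organoid, with every protein extract run in technical quadruplicate on
the mass spectrometer. It is aimed at proteomics analysts who consume
MaxQuant `proteinGroups`-style tables and want the whole path from raw
quantitation to called protein lists, QC and enrichment to be scripted,
tested and reproducible.

## The method

With n = 4 donors and >8000 quantified proteins, multiple-testing-corrected
significance thresholds have little power, so classification rests on
consistency across donors rather than on p-values. After decoy and
contaminant removal, blank-run keratin subtraction, and normalization of
every sample to the lowest total protein abundance, technical replicates
are aggregated and a per-donor ratio is formed for each protein:

    r_d = KD_d / NT_d        (defined when both sides are detected)

A protein is called **DOWN** when every donor with evidence shows a
reduction (all defined r_d < 1, no donor with KD detected but NT not),
r_d ≤ 0.5 in at least 3 of 4 donors — a knockdown reduced to undetectable
while the control is detected counts as a qualifying reduction — and at
most 2 donors are KD-undetectable. **UP** is symmetric: all defined
r_d > 1, r_d ≥ 1.2 in at least 3 of 4, and an undetected side never
qualifies. Proteins detected in fewer than 3 donors are **INELIGIBLE**;
everything else is **NS**. Volcano plots use the mean over donors of
log2 r_d against unadjusted p-values from a paired t-test on
log10-transformed donor values; the classifier itself never consults p.

Supporting statistics: intensity-based absolute quantification
(iBAQ = summed peptide intensity / theoretically observable peptides),
pairwise Pearson correlation of log2 iBAQ over co-detected proteins for
technical QC, hypergeometric over-representation analysis of the called
lists against GMT gene sets within the quantified-proteome universe
(Benjamini–Hochberg FDR), 2^−ΔΔCt qPCR fold changes, and paired
histology thickness ratios (mean ± SEM). A synthetic-data generator
reproduces the full study design with planted effects and known ground
truth, so every stage is testable without any download.

## Worked example

```r
library(consistentprot)

cfg <- synth_config(seed = 7)          # 4 donors x 2 conditions x 4 runs, 9000 proteins
ds  <- generate_dataset(cfg)
res <- run_pipeline(ds$table, ds$design,
                    blank     = generate_blank_run(cfg, ds$table),
                    gene_sets = generate_gene_sets(ds, seed = 8))

table(res$calls$class)
#>       DOWN INELIGIBLE         NS         UP
#>        358        112       8096        434

res$enrichment$DOWN[1:3, c(1, 4:7)]
#>   set_name      set_size overlap p_hypergeom     q_bh
#> 1 DOWN_ENRICHED       50      34    1.43e-36 3.15e-35
#> 2 NULL_SET_06         50       4    1.37e- 1 8.80e- 1
#> 3 NULL_SET_15         50       4    1.37e- 1 8.80e- 1
```

358 proteins are called consistently down-regulated and 434 up-regulated
out of 9000 (the generator plants 450 of each; the near-threshold +0.5
planted effect and detection-limit censoring of strong knockdowns account
for the misses). The planted down-enriched gene set tops the ORA ranking
at q ≈ 3e-35 while the random null sets sit near q = 1. Technical
quadruplicates correlate at Pearson r ≈ 0.99 on this synthetic data
(`res$qc_correlation`). Passing `out_dir =` writes every result table
(`calls.tsv`, `volcano.tsv`, QC and enrichment TSVs) byte-deterministically.

Real data enter through `read_design()`, `read_protein_groups()` and
`read_gmt()`; thresholds are adjustable via `diff_config()`.

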