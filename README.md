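# mitoloc

Per-cell quantification of tail-anchored (TA) protein mislocalization to
mitochondria from multi-channel fluorescence microscopy.

## The problem

TA membrane proteins are inserted into organelle membranes
post-translationally, and insertion is error-prone: the Golgi SNARE Gos28,
for example, accumulates on the mitochondrial outer membrane when the
AAA-ATPase that normally extracts mistargeted TA proteins is missing or
inactive. A live-cell assay for this phenotype images four channels per
field — Hoechst-stained nuclei, an EGFP-tagged reporter, a dye-labelled
transfection marker for the enzyme construct, and MitoTracker-stained
mitochondria — and scores each transfected cell by how strongly the
reporter overlaps the mitochondrial network. mitoloc is a tested R
implementation of that scoring pipeline for anyone running this kind of
mislocalization / colocalization assay, plus a synthetic scene generator
with per-cell ground truth so the whole chain is verifiable without real
images.

The per-cell metric is the Pearson correlation coefficient between the
reporter (x) and mitochondria (y) channels,

    r = Σ(xᵢ − x̄)(yᵢ − ȳ) / sqrt( Σ(xᵢ − x̄)² · Σ(yᵢ − ȳ)² ),

evaluated inside a mitochondria-derived "pseudo-cell" mask and outside the
nucleus. The pipeline stages are: average-intensity z-projection →
per-channel background correction → nucleus segmentation (Otsu) →
propagation of cell-body masks from nucleus seeds → transfection gating on
integrated marker intensity → pseudo-cell mask (threshold + closing + fill
of the mitochondrial stain) → per-cell PCC → condition mean ± SEM,
two-sided Mann-Whitney U comparisons, and Spearman correlation of
expression level with mislocalization. Every cell that drops out carries
an explicit exclusion reason (`not_transfected`, `no_mito_mask`,
`too_few_pixels`, `zero_variance`); nothing is silently discarded.

## Worked example

Simulate a two-condition experiment — an active extractase (mislocalized
fraction θ = 0.05) against an inactive one (θ = 0.60) — and quantify it
end to end:

```r
library(mitoloc)

cfg <- pipeline_config(
  conditions = list(active   = list(misloc_fraction = 0.05),
                    inactive = list(misloc_fraction = 0.60)),
  synth = synth_params(n_fields = 4, n_cells_per_field = 4,
                       transfected_prob = 1),
  segmentation = segmentation_params(marker_gate = 0),
  out_dir = "run", seed = 1)
res <- run_pipeline(cfg)
res$summaries
#>   condition n_cells mean_pcc sem_pcc
#> 1    active      16   -0.222  0.0559
#> 2  inactive      16    0.215  0.0683
res$comparisons
#>   condition_a condition_b  u p_two_sided               method n_a n_b
#> 1      active    inactive 15    2.24e-05 normal_tie_corrected  16  16
```

Cells in the θ = 0.05 condition have negative mean PCC — the reporter sits
on the bright Golgi arc, anti-correlated with the mitochondrial stain —
while θ = 0.60 pushes the mean up by ~0.44, and the Mann-Whitney test
(U = 15 of a possible 256) calls the two conditions apart at p ≈ 2e-5.
`run/per_cell.csv` holds one row per segmented cell with its PCC, pixel
count, integrated marker intensity and exclusion flag;
`run/condition_summary.csv`, `run/comparisons.csv` and `run/manifest.json`
hold the aggregates and provenance (config hash, seed, gate).

The numbered scripts under `analysis/` run the full study at the assay's
published scale (15 fields and ~45 cells per condition, 512×512 fields,
70% transfection efficiency): `01_simulate.R` writes TIFF fields plus
ground truth, `02_quantify.R` re-reads them from disk and quantifies with
an automatically suggested marker gate, `03_group_stats.R` produces the
summary statistics and the per-cell dot plot, and `04_theta_sweep.R` runs
the parameter-recovery studies.

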