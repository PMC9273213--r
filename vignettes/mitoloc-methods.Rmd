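---
title: "Quantifying tail-anchored protein mislocalization to mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tail-anchored protein mislocalization to mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Tail-anchored (TA) membrane proteins are inserted post-translationally and
occasionally end up on the wrong organelle; in particular, Golgi TA SNAREs
such as Gos28 accumulate on the mitochondrial outer membrane when the
AAA-ATPase extractase that normally removes them is absent or inactive. A
live-cell assay for this phenotype images four channels per field — a
nuclear stain (Hoechst), an EGFP-tagged reporter, a dye-labelled
transfection marker for the extractase construct, and a mitochondrial stain
(MitoTracker) — and quantifies, cell by cell, how strongly the reporter
pattern overlaps the mitochondrial network. mitoloc implements that
quantification end to end and pairs it with a synthetic scene generator so
every stage can be validated against known ground truth without any real
images.

The per-cell metric is the Pearson correlation coefficient (PCC) between
the reporter and mitochondria channels,

$$ r \;=\; \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
{\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2}}, $$

evaluated over each cell's measurement pixels: the mitochondria-derived
pseudo-cell mask minus the nucleus. A cell whose reporter sits on the Golgi
has low or negative r (bright reporter where mitochondria are dark); a cell
whose reporter coats the mitochondrial network has r near 1. Condition-level
results are the mean PCC with its SEM (sample sd / sqrt(n)), two-sided
Mann-Whitney U tests between conditions, and a Spearman correlation between
each cell's expression level (integrated marker intensity) and its PCC.

## Pipeline stages and their parameters

1. **Average-intensity z-projection.** Per-pixel arithmetic mean across
   focal planes (never a maximum projection). Single planes pass through
   unchanged.
2. **Background correction** (`correct_background()`), per channel, after
   projection. Default: grayscale morphological opening with a 50 px disc —
   larger than any cell, so cells are removed from the background estimate;
   for speed the opening runs on a 4x block-downsampled copy, which is
   accurate for smooth backgrounds. Alternative: a low-order (<= 3)
   polynomial surface fit to below-median pixels. Whether the original
   assay corrected before or after projection is not something the
   measurement depends on for average projections; this package projects
   first and corrects once, a single documented order.
3. **Nucleus segmentation** (`segment_nuclei()`): Otsu threshold by default
   (or fixed), hole filling, connected components, an area gate of
   80–4000 px, optional distance-transform watershed declumping (off by
   default; synthetic nuclei never touch).
4. **Cell-body propagation** (`propagate_cell_masks()`): each foreground
   pixel of the thresholded guidance channel is assigned to the nucleus
   seed with the smallest accumulated cost along an 8-connected path, with
   step cost `|dI| + lambda * step_length` on the guidance image normalized
   to [0, 1]; `lambda = 0.05` by default. Equal-cost ties go to the lower
   seed label, deterministically. The guidance channel defaults to the
   mitochondria stain — the only broadly cytoplasmic signal in this channel
   set — thresholded, closed (10 px), hole-filled and padded outward by
   5 px (`guidance_grow_px`) because the mitochondrial network stops a few
   pixels short of the plasma membrane.
5. **Transfection gating** (`gate_transfected()`): integrated marker
   intensity per cell, gated at a threshold that the original protocol
   chooses manually from the intensity histogram. The configuration
   therefore requires an explicit value; `marker_gate = "suggest"` derives
   one automatically (Otsu on log1p of the pooled per-cell integrated
   intensities, which are strongly bimodal when an untransfected
   subpopulation exists) for unattended runs. Integrated intensity doubles
   as the expression-level proxy downstream.
6. **Pseudo-cell mask** (`make_pseudo_cell_mask()`): within each gated
   cell, the mitochondria channel is thresholded, morphologically closed
   (10 px disc — wide enough to bridge inter-filament gaps, the "closing
   all gaps" step) and hole-filled into one solid measurement region,
   clipped to its parent cell mask. The closing runs on a zero-padded
   bounding box so the image border never distorts the morphology.
7. **Per-cell PCC** (`per_cell_colocalization()`): plain PCC on all
   measurement pixels — no Costes-style thresholding and no Manders
   coefficients, matching the assay's description. Measurement pixels are
   the pseudo-cell mask minus the *raw* nucleus mask (not a dilated one;
   the choice is a parameter of the measurement region, and the raw mask
   is the simplest faithful reading). Cells with fewer than `min_pixels`
   (default 50) measurement pixels or a constant channel are *excluded
   with a reason*, never imputed and never silently dropped: an undefined
   correlation recorded as 0 would bias condition means toward zero.

## Statistics

`mann_whitney_u()` computes `U = #{(i,j): a_i > b_j} + ties/2`. For
tie-free samples with `n_a + n_b <= 16` the two-sided p-value is exact
(`min(1, 2 * one-sided)` from the null distribution of U); otherwise the
normal approximation with tie correction and continuity correction is used.
Two-sided tests are the conservative, reproducible reading of the assay's
star conventions; both paths are labelled in the output so a reader always
knows which was used. When both groups are entirely tied the variance
vanishes and p = 1. No multiple-testing correction is applied — pairwise
contrasts are reported individually, and the output contains everything
needed to adjust post hoc.

`expression_correlation()` uses Spearman rank correlation (Pearson
available by option) because transient transfection yields a heavily skewed
expression scale; ties get average ranks and the p-value uses the
t-approximation, flagged as approximate below n = 10.

## The synthetic scene generator

`synth_params()` / `generate_condition()` emulate the assay's acquisition:
512x512 fields (EMCCD-like), 15 fields per condition with 3 cells each
(~45 cells per condition, matching the "around 50 cells" scale of the real
experiments), Poisson shot noise, Gaussian read noise (sd 5 counts), a
low-order polynomial background plane, and integer digitization of noisy
images. Each cell carries:

* a circular cell body (radius 38–55 px) and an interior nucleus
  (radius 12–18 px, slightly off-center);
* a mitochondrial network built from 12 correlated random-walk filaments
  (70 steps each) launched at the nucleus rim and confined to the
  cytoplasm, dilated to ~3 px width — a deliberately simple model of the
  spread-out HeLa network phenotype, with no mitochondrial dynamics;
* a compact perinuclear Golgi-like arc (8 px radial band, 120 degrees);
* lognormal marker expression (meanlog log(300), sdlog 0.8) with a
  configurable untransfected subpopulation (default 30%);
* the **mislocalized fraction** `theta`: the fraction of the cell's
  reporter photon mass (6e5 counts) placed uniformly on the mitochondrial
  mask, the remainder on the Golgi mask. `theta` is the single generative
  knob for mislocalization; per-cell PCC rises monotonically with it, which
  is what makes parameter recovery a meaningful end-to-end check.
  Optionally `theta_expression_slope` couples a cell's theta to its
  expression z-score on the logit scale, emulating a dose-dependent
  dominant-negative effect.

Golgi and mitochondrial masks are disjoint by construction (filaments avoid
the arc), so with noise off the reporter mass on the mitochondrial mask is
exactly `theta` of the cell total — the signal-partition property the test
suite asserts to 0.02. Determinism is strict: field i of a condition is
generated under the sub-seed `derive_subseed(master_seed, i)`, so identical
parameters give byte-identical arrays, independently per field.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: optics (no PSF, no chromatic aberration, no
bleed-through), 3-D structure (z-planes are independent noisy renders of
one 2-D scene), cell shape irregularity, touching cells, debris, uneven
staining within a compartment, and photobleaching. Acquisition constants
the original text does not state (z-depth, photon conversion, amplitudes)
are invented defaults, chosen once to give realistic signal-to-background
ratios, and documented here as invented.

## Numerical choices and degenerate inputs

* Images are R matrices indexed `[row, col]`, 1-based, origin top-left —
  one convention across all modules; truths store masks as linear pixel
  indices.
* The propagation metric is the 8-connected (octagonal) geodesic metric;
  on a uniform image it reduces to nearest-seed assignment in that metric,
  which the tests compare against a brute-force Euclidean oracle away from
  bisector ties.
* Blank images segment to zero labels (not an error); a propagation with
  no seeds returns an empty mask; a cell without mitochondrial signal is
  flagged `no_mito_mask` and excluded downstream rather than failing the
  run.
* All randomness flows from explicit seeds in parameter objects; no hidden
  global RNG state survives a call (seeded sections restore the prior RNG
  state).
* TIFF output uses 16-bit samples with an integer intensity scale recorded
  in a JSON sidecar; digitized counts round-trip exactly.

## Problem sizes used by the tests

The validation suite scales the study down where full size adds nothing:
parameter-recovery and contrast experiments run at 10 fields x 5 cells
(50 cells per condition) on full 512 px fields; segmentation recovery uses
24 cells per noise regime; the type-I-error study uses 200 replicate pairs
of 9-cell arms on 192 px fields, measured on ground-truth masks because it
calibrates the statistics, not the segmentation; the Monte-Carlo render
check averages 300 renders of a 64 px field. These sizes are the package's
own choices and are stated here so they can be revisited.

## Known limitations

* The pseudo-cell area proxy inherits the assay's assumption that the
  mitochondrial network spans the cytoplasm; cells with collapsed or
  fragmented networks get smaller measurement regions, which the exclusion
  flags surface but do not correct.
* The automatic gate stand-in is conservative when expression is strongly
  skewed: low expressors near the histogram valley may be dropped, as a
  manual gate would also tend to do.
* PCC is computed on background-corrected intensities in both channels — a
  single documented convention; results on data corrected differently per
  channel may shift slightly.
* Segmentation is classical (threshold + propagation); no learned models,
  no tracking, no 3-D segmentation.
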