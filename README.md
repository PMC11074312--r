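# episwitch

Quantitative single-cell analysis of a bistable transcription-factor
switch in pluripotent stem-cell colonies.

When mouse embryonic stem cells exit the naive pluripotent state, an
inducing factor (OCT6, reported by an mCherry cassette) and the naive
factor NANOG become mutually exclusive: as the driver rises above image
background, the response factor switches OFF in an all-or-none,
dose-dependent fashion, and colonies change from tightly packed domes to
spread fields with detached cells. `episwitch` implements the analyses
that establish such a switch from single-cell data:

* **Imaging** — background subtraction, classical marker-controlled
  watershed segmentation of a DAPI channel, per-nucleus mean intensities
  and centroids (`subtract_background()`, `segment_nuclei()`,
  `measure_nuclei()`); externally produced masks can be imported with
  `read_labels()`.
* **Bistability statistics** — fold-over-background normalization
  (`fold = intensity / background`), ON/OFF classification by a
  2-component Gaussian mixture on log intensities or a fold threshold,
  the dose–response curve of the response-negative fraction over fold
  bins `[0,1.5) [1.5,2) [2,4) [4,∞)`, log-scale channel correlation, and
  equal-count Low/Med/High gating. The ON probability in the synthetic
  generator follows a repressive Hill link
  `P(ON | f) = 1 / (1 + (f/f_half)^h)`.
* **Colony packing** — exact nearest-neighbor distance distributions and
  a two-sample Kolmogorov–Smirnov comparison.
* **smFISH** — Laplacian-of-Gaussian filtering, maximum-intensity
  projection, robust spot calling (median + 5·MAD), per-cell transcript
  counts.
* **Enrichment** — GREAT-style basal-plus-extension peak-to-gene
  assignment (5 kb up / 1 kb down / 1 Mb extension, BED 0-based
  half-open) and a 10,000-iteration bootstrap null for the overlap
  between a DE gene list and peak-bearing genes, with add-one empirical
  p-values.
* **qPCR** — geometric-mean GAPDH/PGK1 normalization, log2 relativization
  to a control condition, randomized-block ANOVA with Tukey compact
  letter display.

A seeded synthetic-data generator (`generate_colony_image()`,
`generate_cell_table()`, `generate_spot_stack()`,
`generate_gene_universe()`, `generate_qpcr_table()`) produces images,
cell tables, FISH stacks, gene universes and N0 tables with known ground
truth, so the whole pipeline is testable without any raw data.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data (`Rscript analysis/01_simulate_colonies.R`, then `02` … `07`),
writing tables under `results/`. The core of the bistability analysis:

```r
library(episwitch)

ep    <- expression_params(f_half = 2, h = 6, seed = 103)
cells <- generate_cell_table(5000, ep)

fold  <- fold_over_background(cells$mCherry, 100)
state <- classify_on_off(cells$NANOG, "gmm2_log")
dose_response(fold, state$state)
```

```
       bin n_cells fraction_negative ci_lo  ci_hi
1 negative    1470            0.0272 0.020 0.0368
2      low     179            0.3408 0.275 0.4129
3     2-4x     800            0.8850 0.861 0.9053
4     >=4x    2551            0.9984 0.996 0.9994
```

Cells at background fold are almost all response-positive; at 2–4× fold
most are already response-negative, and essentially all are negative
beyond 4× — the dose-dependent bistable signature. Gating the same cells
into equal thirds by driver level gives 93%, 6% and 0% response-positive
cells in the Low, Med and High gates, and the packing analysis
(`analysis/04_colony_packing.R`) reports median nearest-neighbor
distances of 17.7 px (tight mode) vs 20.5 px (spread mode), KS p < 0.001.
The enrichment analysis (`analysis/06_enrichment.R`) tests a planted DE
list of 292 genes with 114 peak-bearing members against its bootstrap
null:

```
Bootstrap peak/DE-gene overlap
  observed: 114 of 292
  null:     40.02 +/- 4.96 (10000 iterations)
  fold:     2.849
  p:        9.999e-05
```

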