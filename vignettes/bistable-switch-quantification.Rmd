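---
title: "Quantifying a bistable transcription-factor switch in stem-cell colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a bistable transcription-factor switch in stem-cell colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episwitch)
```

## The biological setting and the model

During the exit from naive pluripotency, mouse embryonic stem cells
dismantle the naive gene regulatory network and acquire a formative
identity. A hallmark of this transition is the mutually exclusive
expression of an inducing transcription factor (OCT6, reported by an
mCherry co-expression cassette) and the naive factor NANOG: cells with the
driver above background lose the response factor in an all-or-none,
dose-dependent fashion, consistent with a double-negative feedback loop
acting as a toggle switch.

`episwitch` implements the quantitative analyses by which such a switch is
established from single-cell data, together with a synthetic-data generator
that encodes the expected statistical structure so every stage can be
validated against known ground truth.

The generator's core is a repressive Hill link between the driver's
fold over background $f$ and the probability that the response gene is ON:

$$P(\mathrm{ON} \mid f) = \frac{1}{1 + (f/f_{1/2})^{h}}$$

with half-repression fold $f_{1/2}$ (default 2, in fold-over-background
units) and steepness $h$ (default 6, unitless). These defaults place
half-repression at twice background with a sharp but not step-like
transition, which reproduces the qualitative single-cell pattern reported
for the OCT6&ndash;NANOG pair: cells at background fold are predominantly
response-positive, more than 40% of cells are response-negative already in
the 2&ndash;4&times; bin, and more than 90% are negative beyond 4&times;.
Per-cell intensities are drawn from ON/OFF log-normal mixtures per channel;
ON and OFF states differ in their log-mean. Driver-negative cells still
receive background-level signal, so their fold is ~1 &mdash; folds are
ratios of measured intensity to the image background estimate, not
background-subtracted differences, because "two-fold above background"
reads most naturally as a ratio.

## What the generator emulates, and what it does not

The colony generator renders nuclei as hard disks with a 1-px Gaussian
edge blur over a uniform background, with Poisson shot noise plus additive
Gaussian read noise (sd 3 counts by default). This matches the first-order
statistics of fluorescence imaging and stresses background subtraction and
segmentation, which is all the downstream statistics need. Two packing
modes encode the morphological contrast of interest: `tight` draws nucleus
centers inside small colony disks near the minimum center separation
(2 &times; radius by default, with at most 5% overlap), as in compact
dome-shaped colonies; `spread` uses larger, freely interleaving colony
disks plus a 15% fraction of colony-detached singletons, as in flattened
differentiating cultures. Defaults (nucleus radius 8 &plusmn; 0.8 px,
18&ndash;20 nuclei per colony, 512&sup2; fields, background 100 counts)
are free choices at the scale of a 20&times; micrograph; the source study
reports no pixel size or intensity calibration, so absolute units are
arbitrary and only ratios and distances carry meaning.

The generator does **not** emulate photorealistic textures, 3-D nuclear
shapes, chromatin substructure, cell-cycle intensity variation,
illumination gradients, or temporal dynamics. Passing tests therefore
demonstrate that the algorithms recover known structure under realistic
noise and packing, not that they are robust to every artifact of real
micrographs; segmentation in particular remains pluggable
(`read_labels()`) so externally produced masks, e.g. from a trained
star-convex model, can replace the built-in classical pipeline.

The smFISH generator places per-cell transcript spots uniformly inside
cell masks with a minimum separation of 5 px (&asymp;3.3&sigma; of the
default 1.5-px spot width). Diffraction-limited spots closer than that are
unresolvable even in principle &mdash; their blob responses interfere and
merge &mdash; so the generator draws only resolvable configurations, which
is what per-cell *count* recovery presupposes. Absolute count calibration
against the source data is untestable (the study shows presence/absence),
so tests assert recovery of the generator's own truth and the
direction of the repressor-high vs repressor-low contrast.

## Imaging pipeline choices

* **Background.** The default estimator takes the 25th percentile of a
  lightly smoothed (Gaussian, 2 px) copy of the image, snapped to the
  nearest observed pixel value. Smoothing matters: shot noise at
  background level 100 has sd &asymp;10, so the raw 25th percentile would
  read ~7% low; after smoothing the estimate is within 1% of the true
  level. A rolling-ball variant (grayscale opening with a disc) is
  provided for fields with spatial background structure.
* **Segmentation.** Gaussian smoothing (&sigma; = 1 px), Otsu threshold,
  hole filling, then distance-transform peaks (minimum separation 6 px,
  minimum height 2.5 px) as markers for watershed-style propagation on the
  inverted distance map. Marker-controlled propagation splits touching
  nuclei far more reliably than tolerance-based basin merging: on
  tight-packing fixtures with 100 touching nuclei it recovers
  100 &plusmn; 0 nuclei at mean mask IoU &asymp; 0.9. The area filter
  defaults to [0.3, 3] &times; the median detected area, removing debris
  and merged blobs without absolute pixel-size knowledge.
* **Centroids.** Pixel centers sit at integer coordinates, origin
  top-left, x = column, y = row; centroids are unweighted means of member
  pixel coordinates. This convention is fixed so that spatial statistics
  are reproducible across implementations.

## Single-cell statistics

Fold bins default to [0, 1.5), [1.5, 2), [2, 4), [4, &infin;), labelled
negative / low / 2&ndash;4&times; / &ge;4&times;; the 2 and 4 edges are the
conventional fold thresholds for this switch and the 1.5 edge separates
background-level cells from weakly induced ones. Threshold classification
is inclusive (fold &ge; cutoff &rArr; ON); a fixed convention is required,
and ties at the cutoff are vanishingly rare in float data. The
two-component mixture classifier fits Gaussians on log intensities via
mclust's deterministic model-based initialization (hierarchical
agglomeration); we preferred this to seeded k-means++ restarts because it
is exactly reproducible without random-number bookkeeping and is the
standard R implementation. The classifier reports the separation statistic
$D = |\mu_1-\mu_2| / \sqrt{(\sigma_1^2+\sigma_2^2)/2}$; recovery of ON
fractions to &plusmn;0.05 is only claimed for $D \ge 3$ and n &ge; 500,
and degenerate inputs (all values equal) yield a flagged single-population
verdict rather than an error. Channel correlations are computed on log10
intensities by default because nuclear intensities span orders of
magnitude. Equal-count gating ranks cells and splits them into three
contiguous rank groups; any remainder goes to Low first, then Med, and
ties are broken by stable input order so identical values still yield
balanced gates.

## Spatial statistics

Nearest-neighbor distances are exact Euclidean distances to the closest
other centroid, computed blockwise (so memory stays bounded) and tested
for exact equality against an all-pairs oracle. Distances are reported in
pixels; no edge correction is applied at image borders &mdash; cells near
the border can only have neighbors on one side, which biases their
distances slightly upward. This bias is shared by both conditions being
compared and is accepted as a known limitation. The two-sample
Kolmogorov&ndash;Smirnov test was chosen for the tight-vs-spread
comparison; the source analysis shows the distributions without naming a
test, so the choice is declared here.

## smFISH detection

Detection follows the stated order of operations: the Laplacian-of-Gaussian
filter (scale-normalized, negated, zero-mean kernel) is applied per z-plane
first, then the maximum-intensity projection is taken, then local maxima
above threshold are called with greedy non-maximum suppression inside
3 px. The default threshold is median + 5 &times; MAD of the filtered
projection &mdash; robust to spot density, and declared as a package
default since the source gives none. Detection counts are monotone
non-increasing in the threshold by construction (raising the threshold can
only remove candidates, and any suppressor of a surviving candidate also
survives).

## Enrichment

Peak-to-gene assignment re-implements the basal-plus-extension rule
locally: each gene's basal domain spans 5 kb upstream to 1 kb downstream
of its TSS (strand-aware); domains extend both ways up to 1 Mb but never
into a neighboring basal domain; a gene is flagged when any peak overlaps
its extended domain, with BED-style 0-based half-open coordinates
throughout. The bootstrap null draws gene sets of the DE-list size without
replacement within an iteration (a DE list is a set), 10,000 iterations by
default, and the empirical p uses the add-one convention
$(r+1)/(B+1)$ so that p is never exactly zero. On a synthetic universe of
1000 genes with 137 peak-bearing (the ~14% by-chance rate reported for
this system), draws of 292 give a null mean of 40.0 &mdash; the "expected
by chance" count &mdash; and a planted observed 114 is ~2.85-fold
enriched, p &le; 10&#8315;&sup3;. The gene universe for a real analysis is
an explicit input; the package never silently defaults it.

## qPCR

Starting quantities (N0, as emitted by amplification-curve software) are
normalized per sample to the geometric mean of GAPDH and PGK1, log2
transformed (log2 is the convention for expression fold changes; the
source says only "log-transformed"), and relativized to the mean of the
control condition's replicates per gene &mdash; so control replicates
average exactly zero. The condition test is an additive randomized-block
ANOVA (condition + replicate block, no interaction, one observation per
cell); incomplete blocks are an error, never imputed. Pairwise Tukey
contrasts at &alpha; = 0.05 are summarized as a compact letter display via
multcomp. Under a pure-noise null the condition test holds its nominal
size (type-I error &asymp; 0.04&ndash;0.06 over 1000 simulations).

## Reproducibility and problem sizes

All generators take explicit integer seeds and are byte-reproducible;
`run_pipeline()` derives every stage's seed from the single configuration
seed and writes a manifest of MD5 hashes, so identical configurations
reproduce identical outputs bit for bit. The bundled tests and the
acceptance script work at deliberately desk-sized scales &mdash; 512&sup2;
to 1024&sup2; fields with 100&ndash;300 nuclei, 5000-cell dose-response
tables, 1000-gene universes with 10,000 bootstrap iterations, 600-spot
FISH stacks, 1000 ANOVA null simulations &mdash; chosen as the smallest
sizes at which the binomial/bootstrap error bounds quoted above are
meaningful.

## Known limitations

* Segmentation assumes roughly convex, similarly sized nuclei; strongly
  elongated or overlapping (>5%) nuclei will be merged or split.
* The scalar percentile background is global; vignetting or spatial
  background structure requires the rolling-ball variant.
* No edge correction in nearest-neighbor statistics (see above).
* The mixture classifier can misassign cells when the two log-intensity
  components are closer than D &asymp; 3.
* The Hill-linked generator models a static snapshot; it cannot be used to
  study switching kinetics, hysteresis, or lineage history.
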