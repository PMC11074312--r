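#!/usr/bin/env Rscript
# Quantify the simulated micrographs: background, nuclear segmentation of
# the DAPI channel, and per-nucleus mean intensities for every channel.

library(episwitch)

indir <- "results/simulated"
outdir <- "results/quantified"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

channels <- c("DAPI", "mCherry", "NANOG")
for (cond in c("wt", "ko")) {
  imgs <- lapply(channels, function(ch) {
    read_image(file.path(indir, paste0(cond, "_", ch, ".tif")))
  })
  names(imgs) <- channels
  labels <- segment_nuclei(imgs$DAPI)
  cells <- measure_nuclei(labels, imgs)
  write_labels(labels, file.path(outdir, paste0(cond, "_labels.tif")))
  write_table_auto(cells, file.path(outdir, paste0(cond, "_cells.tsv")))

  truth <- read_table_auto(file.path(indir, paste0(cond, "_truth.tsv")))
  bg <- subtract_background(imgs$mCherry, "percentile", p = 25)$background
  cat(sprintf(
    "%s: %d nuclei detected (%d simulated); mCherry background %.1f\n",
    cond, nrow(cells), nrow(truth), bg))
}
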