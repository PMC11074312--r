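#!/usr/bin/env Rscript
# Simulate the two imaging conditions the downstream analyses contrast:
# a spread, loosely packed field (WT-like differentiating colonies, with
# colony-detached cells) and a tightly packed field (KO-like colonies),
# plus a large image-free single-cell table for the dose-response analysis.

library(episwitch)

outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (cond in c("wt", "ko")) {
  mode <- if (cond == "wt") "spread" else "tight"
  cp <- colony_params(n_colonies = 6, nuclei_per_colony = 18,
                      packing_mode = mode, image_shape_px = c(512, 512),
                      seed = if (cond == "wt") 101 else 102)
  ep <- expression_params(seed = cp$seed)
  sim <- generate_colony_image(cp, ep)
  for (ch in names(sim$image$channels)) {
    write_image(sim$image$channels[[ch]],
                file.path(outdir, paste0(cond, "_", ch, ".tif")))
  }
  write_table_auto(sim$truth, file.path(outdir, paste0(cond, "_truth.tsv")))
  cat(sprintf("%s field: %d nuclei in %s mode\n",
              cond, nrow(sim$truth), mode))
}

# image-free cell table under the calibrated repressive Hill link
ep <- expression_params(f_half = 2, h = 6, seed = 103)
cells <- generate_cell_table(5000, ep)
write_table_auto(cells, file.path(outdir, "dox_cells.tsv"))
cat(sprintf("dose-response table: %d cells, %.0f%% driver-positive\n",
            nrow(cells), 100 * mean(cells$driver_positive)))
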