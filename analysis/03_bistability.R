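#!/usr/bin/env Rscript
# The bistability analysis: how the response channel (NANOG) switches OFF
# as the driver channel (mCherry, a proxy for OCT6) rises above background.
# Produces the dose-response curve over fold-over-background bins, the
# driver/response correlation, and the equal-count Low/Med/High gating.

library(episwitch)

outdir <- "results/bistability"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cells <- read_table_auto("results/simulated/dox_cells.tsv")
bg <- 100  # the generator's background level; for images this comes from
           # subtract_background() on the driver channel

fold_driver <- fold_over_background(cells$mCherry, bg)
fold_resp <- fold_over_background(cells$NANOG, bg)

# ON/OFF state of the response channel from its log-intensity mixture
cls <- classify_on_off(cells$NANOG, "gmm2_log")
cat(sprintf("response mixture: separation D = %.1f, %.0f%% of cells ON\n",
            cls$D, 100 * mean(cls$state)))

curve <- dose_response(fold_driver, cls$state)
write_table_auto(curve, file.path(outdir, "dose_response.tsv"))
print(as.data.frame(curve), digits = 3)
key <- function(b) 100 * curve$fraction_negative[curve$bin == b]
cat(sprintf(
  "response-negative: %.0f%% in the negative bin, %.0f%% at 2-4x, %.0f%% beyond 4x\n",
  key("negative"), key("2-4x"), key(">=4x")))

# driver intensity correlates with itself across channels in log space
corr <- correlate_channels(cells$mCherry, cells$NANOG, log = TRUE)
cat(sprintf("log10 mCherry vs log10 NANOG: r = %.2f (n = %d)\n",
            corr$r, corr$n))

gates <- gate_equal_thirds(cells$mCherry)
by_gate <- tapply(cls$state, gates, mean)
gate_tab <- data.frame(gate = names(by_gate),
                       n = as.vector(table(gates)),
                       pct_response_positive = round(100 * as.vector(by_gate), 1))
write_table_auto(gate_tab, file.path(outdir, "gates.tsv"))
cat("equal-count mCherry gates, % response-positive:\n")
print(gate_tab, row.names = FALSE)
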