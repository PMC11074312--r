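#!/usr/bin/env Rscript
# qPCR analysis: normalize starting quantities to the geometric mean of the
# GAPDH/PGK1 housekeeping pair, relativize to the naive-condition mean, and
# test condition effects per gene with a randomized-block ANOVA plus Tukey
# compact letter display.

library(episwitch)

outdir <- "results/qpcr"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genes <- c("Nanog", "Sox3", "Oct6")
conditions <- c("2i+LIF", "EpiLC24h", "EpiLC48h")
effects <- matrix(c(0, -1.5, -2.5,    # Nanog falls during differentiation
                    0, 2.0, 3.0,      # Sox3 rises
                    0, 3.0, 4.0),     # Oct6 rises
                  nrow = 3, byrow = TRUE)
tab <- generate_qpcr_table(genes, conditions, n_blocks = 3,
                           effects = effects, seed = 701)
norm <- normalize_expression(tab, control_condition = "2i+LIF")
write_table_auto(norm, file.path(outdir, "normalized.tsv"))

rows <- lapply(genes, function(g) {
  sub <- norm[norm$gene == g, ]
  fit <- rbd_anova_tukey(sub$rel_log2_expr, sub$condition, sub$replicate)
  cat(sprintf("%-6s F = %6.1f, p = %.2g, letters: %s\n", g, fit$F, fit$p,
              paste(names(fit$letters), unname(fit$letters),
                    sep = "=", collapse = " ")))
  data.frame(gene = g, F = fit$F, p = fit$p,
             letters = paste(names(fit$letters), unname(fit$letters),
                             sep = "=", collapse = ";"))
})
write_table_auto(do.call(rbind, rows), file.path(outdir, "anova.tsv"))
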