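#' Simulate a gene universe with a known peak-bearing fraction
#'
#' Places gene TSSs on a single chromosome with a guaranteed minimum gap (so
#' basal regulatory domains never overlap), flags `round(n_genes *
#' peak_fraction)` genes, and writes one short peak inside each flagged
#' gene's basal domain. By construction, [assign_peaks_to_genes()] with the
#' default rule recovers the planted flags exactly.
#'
#' @param n_genes Number of genes.
#' @param peak_fraction Fraction of genes bearing a peak, in `[0, 1]`.
#' @param genome_length Chromosome length in bp; must accommodate all TSSs
#'   at the minimum gap, otherwise an explicit error is raised.
#' @param chrom Chromosome name.
#' @param peak_width Width of each planted peak (bp).
#' @param min_gap_bp Minimum distance between consecutive TSSs; the default
#'   20 kb keeps basal domains (5 kb up / 1 kb down) disjoint.
#' @param seed Integer seed.
#' @return A list: `genes`, a `GeneUniverse` tibble (`gene_id`, `chrom`,
#'   `tss`, `strand`, `has_peak` — the planted truth), and `peaks`, a
#'   0-based half-open BED tibble (`chrom`, `start`, `end`).
#' @export
generate_gene_universe <- function(n_genes, peak_fraction,
                                   genome_length = 5e7, chrom = "chr1",
                                   peak_width = 200, min_gap_bp = 2e4,
                                   seed = 1L) {
  stopifnot(n_genes >= 1, peak_fraction >= 0, peak_fraction <= 1,
            peak_width >= 1, min_gap_bp > 12000)
  margin <- 1e4
  if (genome_length < n_genes * min_gap_bp + 2 * margin) {
    stop("genome too short to place ", n_genes, " TSSs at a ", min_gap_bp,
         " bp minimum gap without collision", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    slack <- genome_length - 2 * margin - (n_genes - 1) * min_gap_bp
    u <- sort(runif(n_genes, 0, slack))
    tss <- round(margin + u + (seq_len(n_genes) - 1) * min_gap_bp)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    n_flag <- round(n_genes * peak_fraction)
    flagged <- sort(sample.int(n_genes, n_flag))
    has_peak <- seq_len(n_genes) %in% flagged
    genes <- tibble::tibble(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom, tss = tss, strand = strand, has_peak = has_peak
    )
    # peak centered on the TSS sits inside the basal domain on either strand
    peaks <- tibble::tibble(
      chrom = chrom,
      start = pmax(0, tss[flagged] - peak_width %/% 2),
      end = tss[flagged] + peak_width %/% 2
    )
    list(genes = genes, peaks = peaks)
  })
}

# Basal-plus-extension regulatory domains, 0-based half-open.
# basal: 5' up / 3' down of the TSS, strand-aware; extension grows each side
# up to extension_bp but stops at the nearest neighboring basal domain.
regulatory_domains <- function(genes, basal_up_bp, basal_down_bp, extension_bp) {
  basal_start <- ifelse(genes$strand == "+",
                        genes$tss - basal_up_bp, genes$tss - basal_down_bp)
  basal_end <- ifelse(genes$strand == "+",
                      genes$tss + basal_down_bp, genes$tss + basal_up_bp)
  basal_start <- pmax(basal_start, 0)
  out <- genes
  out$ext_start <- NA_real_; out$ext_end <- NA_real_
  for (chr in unique(genes$chrom)) {
    i <- which(genes$chrom == chr)
    ord <- i[order(basal_start[i])]
    bs <- basal_start[ord]; be <- basal_end[ord]
    prev_end <- c(-Inf, cummax(be))[seq_along(ord)]
    next_start <- rev(c(Inf, cummin(rev(bs)))[seq_along(ord)])
    es <- pmax(bs - extension_bp, pmin(pmax(prev_end, 0), bs))
    ee <- pmin(be + extension_bp, pmax(next_start, be))
    out$ext_start[ord] <- pmax(es, 0)
    out$ext_end[ord] <- ee
  }
  out
}

#' Assign peaks to genes by a GREAT-style basal-plus-extension rule
#'
#' Each gene receives a basal regulatory domain around its TSS
#' (`basal_up_bp` upstream / `basal_down_bp` downstream, strand-aware). The
#' domain is then extended on both sides up to `extension_bp`, but never
#' into a neighboring gene's basal domain. A gene is flagged `has_peak` when
#' any peak overlaps its extended domain (0-based half-open overlap).
#'
#' @param peaks BED tibble/data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @param genes `GeneUniverse` tibble with `gene_id`, `chrom`, `tss`
#'   (0-based), `strand`.
#' @param basal_up_bp,basal_down_bp,extension_bp Rule parameters; defaults
#'   are the published basal-plus-extension defaults (5 kb / 1 kb / 1 Mb).
#' @return The `genes` tibble with a recomputed logical `has_peak` column.
#' @export
assign_peaks_to_genes <- function(peaks, genes,
                                  basal_up_bp = 5000, basal_down_bp = 1000,
                                  extension_bp = 1e6) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)),
            !anyDuplicated(genes$gene_id), all(genes$tss >= 0),
            all(genes$strand %in% c("+", "-")))
  dom <- regulatory_domains(genes, basal_up_bp, basal_down_bp, extension_bp)
  if (nrow(peaks) == 0) {
    genes$has_peak <- FALSE
    return(genes)
  }
  # convert 0-based half-open to 1-based closed for GRanges
  gr_dom <- GenomicRanges::GRanges(
    dom$chrom, IRanges::IRanges(dom$ext_start + 1, dom$ext_end))
  gr_peak <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- GenomicRanges::countOverlaps(gr_dom, gr_peak)
  genes$has_peak <- hits > 0
  genes
}

#' Bootstrap null for a resampled peak-bearing gene count
#'
#' Draws `n_iter` random gene sets of size `n_draw` from the universe and
#' counts peak-bearing genes in each, giving the null distribution for the
#' overlap expected by chance.
#'
#' @param universe `GeneUniverse` tibble with a logical `has_peak` column.
#' @param n_draw Genes per draw (e.g. the size of a DE gene list).
#' @param n_iter Number of bootstrap iterations (default 10000).
#' @param replace Sample genes with replacement within an iteration? The
#'   default `FALSE` draws gene sets, matching a fixed-size DE list.
#' @param seed Integer seed.
#' @return Integer vector of `n_iter` null overlap counts.
#' @export
bootstrap_null <- function(universe, n_draw, n_iter = 10000,
                           replace = FALSE, seed = 1L) {
  stopifnot("has_peak" %in% names(universe), is.logical(universe$has_peak),
            n_draw >= 1, n_iter >= 1)
  if (!replace && n_draw > nrow(universe)) {
    stop("cannot draw ", n_draw, " genes without replacement from a universe of ",
         nrow(universe), call. = FALSE)
  }
  flags <- universe$has_peak
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_iter),
           function(i) sum(flags[sample.int(length(flags), n_draw,
                                            replace = replace)]),
           integer(1))
  })
}

#' Empirical p-value against a resampling null
#'
#' Uses the add-one convention `p = (r + 1) / (n + 1)` with `r` the number
#' of null values at or above the observation, so p is never exactly zero.
#'
#' @param null Numeric vector of null statistics.
#' @param observed Observed statistic.
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_p <- function(null, observed) {
  (sum(null >= observed) + 1) / (length(null) + 1)
}

#' Bootstrap enrichment of peak-bearing genes in a DE gene list
#'
#' Counts how many genes of a differential-expression list bear a peak
#' (per the universe's `has_peak` flags) and compares that count with the
#' bootstrap null of [bootstrap_null()].
#'
#' @param de_genes Character vector of gene ids; all must be present in the
#'   universe, otherwise the missing ids are reported in the error.
#' @param universe `GeneUniverse` tibble with `gene_id` and logical
#'   `has_peak`.
#' @param n_iter,replace,seed Passed to [bootstrap_null()].
#' @return An `enrichment_result` list: `observed`, `n_draw`, `null_mean`,
#'   `null_sd`, `fold` (`observed / null_mean`), `empirical_p`, `null`
#'   (the full null vector).
#' @export
bootstrap_overlap <- function(de_genes, universe, n_iter = 10000,
                              replace = FALSE, seed = 1L) {
  stopifnot(is.character(de_genes), length(de_genes) >= 1)
  idx <- match(de_genes, universe$gene_id)
  if (anyNA(idx)) {
    stop("DE genes absent from the universe: ",
         paste(de_genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  observed <- sum(universe$has_peak[idx])
  null <- bootstrap_null(universe, length(de_genes), n_iter, replace, seed)
  structure(
    list(observed = observed, n_draw = length(de_genes),
         null_mean = mean(null), null_sd = sd(null),
         fold = observed / mean(null),
         empirical_p = empirical_p(null, observed),
         null = null),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Bootstrap peak/DE-gene overlap\n",
      "  observed: ", x$observed, " of ", x$n_draw, "\n",
      "  null:     ", signif(x$null_mean, 4), " +/- ", signif(x$null_sd, 3),
      " (", length(x$null), " iterations)\n",
      "  fold:     ", signif(x$fold, 4), "\n",
      "  p:        ", format(x$empirical_p), "\n", sep = "")
  invisible(x)
}

#' Screen for persistently induced transcription factors
#'
#' Selects genes that are significantly upregulated early in a transition
#' and remain upregulated later: FDR below `fdr` and log2 fold change above
#' `min_lfc` at the early timepoint, log2 fold change above `min_lfc` at the
#' late timepoint, intersected with a transcription-factor id set.
#'
#' @param lfc_table Tibble/data frame with columns `gene`, `log2fc_early`,
#'   `fdr_early`, `log2fc_late`.
#' @param tf_ids Character vector of transcription-factor gene ids.
#' @param fdr FDR cutoff at the early timepoint (default 0.1).
#' @param min_lfc Minimum log2 fold change at both timepoints (default 1).
#' @return The qualifying rows, sorted by `log2fc_late` descending.
#' @export
screen_persistent_tfs <- function(lfc_table, tf_ids, fdr = 0.1, min_lfc = 1) {
  need <- c("gene", "log2fc_early", "fdr_early", "log2fc_late")
  if (!all(need %in% names(lfc_table))) {
    stop("lfc_table is missing columns: ",
         paste(setdiff(need, names(lfc_table)), collapse = ", "), call. = FALSE)
  }
  hit <- lfc_table$fdr_early < fdr &
    lfc_table$log2fc_early > min_lfc &
    lfc_table$log2fc_late > min_lfc &
    lfc_table$gene %in% tf_ids
  out <- lfc_table[which(hit), , drop = FALSE]
  out[order(-out$log2fc_late), , drop = FALSE]
}
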