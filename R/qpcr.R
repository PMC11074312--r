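#' Simulate a qPCR starting-quantity (N0) table
#'
#' Generates per-gene, per-condition, per-replicate N0 values on a log2
#' scale: `log2 N0 = base + condition effect + block effect + noise`, then
#' exponentiated. Housekeeping genes have zero condition effect by
#' construction.
#'
#' @param genes Character vector of target gene names.
#' @param conditions Character vector of condition names; the first is the
#'   control unless stated otherwise downstream.
#' @param n_blocks Number of biological replicates (blocks).
#' @param effects Numeric matrix of true log2 condition effects,
#'   `length(genes)` x `length(conditions)` (dimnames optional); defaults to
#'   all-zero.
#' @param housekeeping Housekeeping gene names appended to the table with
#'   zero effect.
#' @param block_sd,noise_sd Standard deviations of the block effect and the
#'   residual noise on the log2 scale.
#' @param base_log2 Baseline log2 N0.
#' @param seed Integer seed.
#' @return A `QpcrTable` tibble: `gene`, `replicate`, `condition`, `N0`.
#' @export
generate_qpcr_table <- function(genes, conditions, n_blocks = 3,
                                effects = NULL,
                                housekeeping = c("GAPDH", "PGK1"),
                                block_sd = 0.3, noise_sd = 0.25,
                                base_log2 = 4, seed = 1L) {
  stopifnot(length(genes) >= 1, length(conditions) >= 2, n_blocks >= 2)
  if (is.null(effects)) {
    effects <- matrix(0, length(genes), length(conditions))
  }
  stopifnot(nrow(effects) == length(genes), ncol(effects) == length(conditions))
  all_genes <- c(genes, housekeeping)
  eff <- rbind(effects, matrix(0, length(housekeeping), length(conditions)))
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(gene = all_genes, replicate = seq_len(n_blocks),
                        condition = conditions, stringsAsFactors = FALSE)
    block_eff <- rnorm(n_blocks, 0, block_sd)
    gi <- match(grid$gene, all_genes)
    ci <- match(grid$condition, conditions)
    l2 <- base_log2 + eff[cbind(gi, ci)] + block_eff[grid$replicate] +
      rnorm(nrow(grid), 0, noise_sd)
    tibble::tibble(gene = grid$gene, replicate = as.integer(grid$replicate),
                   condition = grid$condition, N0 = 2^l2)
  })
}

#' Normalize qPCR expression to housekeeping genes
#'
#' Per sample (one replicate of one condition), each target gene's N0 is
#' divided by the geometric mean of the housekeeping genes' N0 values, the
#' ratio is log2-transformed, and the result is relativized to the mean log2
#' value of the control condition's replicates for that gene. Control
#' replicates therefore average exactly zero for every gene.
#'
#' @param table `QpcrTable` tibble with columns `gene`, `replicate`,
#'   `condition`, `N0` (all N0 > 0).
#' @param housekeeping Housekeeping gene names; every sample must contain
#'   all of them.
#' @param control_condition Condition to relativize against.
#' @return A tibble `gene`, `replicate`, `condition`, `rel_log2_expr` for
#'   the non-housekeeping genes.
#' @export
normalize_expression <- function(table, housekeeping = c("GAPDH", "PGK1"),
                                 control_condition) {
  need <- c("gene", "replicate", "condition", "N0")
  stopifnot(all(need %in% names(table)))
  if (any(!is.finite(table$N0) | table$N0 <= 0)) {
    stop("all N0 values must be positive and finite", call. = FALSE)
  }
  if (!control_condition %in% table$condition) {
    stop("control condition '", control_condition, "' absent from the table",
         call. = FALSE)
  }
  samples <- unique(table[, c("replicate", "condition")])
  geo <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sub <- table[table$replicate == samples$replicate[i] &
                   table$condition == samples$condition[i], ]
    hk <- sub$N0[match(housekeeping, sub$gene)]
    if (anyNA(hk)) {
      stop("sample replicate=", samples$replicate[i], " condition='",
           samples$condition[i], "' is missing housekeeping genes: ",
           paste(housekeeping[is.na(hk)], collapse = ", "), call. = FALSE)
    }
    geo[i] <- exp(mean(log(hk)))
  }
  targets <- table[!table$gene %in% housekeeping, ]
  si <- match(paste(targets$replicate, targets$condition),
              paste(samples$replicate, samples$condition))
  l2 <- log2(targets$N0 / geo[si])
  out <- tibble::tibble(gene = targets$gene, replicate = targets$replicate,
                        condition = targets$condition, log2_ratio = l2)
  ctrl <- out[out$condition == control_condition, ]
  ctrl_mean <- tapply(ctrl$log2_ratio, ctrl$gene, mean)
  out$rel_log2_expr <- out$log2_ratio - as.numeric(ctrl_mean[out$gene])
  out[, c("gene", "replicate", "condition", "rel_log2_expr")]
}

#' Randomized-block ANOVA with Tukey compact letter display
#'
#' Fits the additive two-way model `value ~ condition + block` (no
#' interaction; one observation per cell), tests the condition effect, and
#' summarizes all pairwise Tukey contrasts at `alpha` as a compact letter
#' display: conditions sharing a letter are not significantly different.
#' Blocks must be complete (every condition observed in every block); no
#' imputation is performed.
#'
#' @param values Numeric response (e.g. relative log2 expression).
#' @param condition Condition factor/vector.
#' @param block Replicate (block) factor/vector.
#' @param alpha Family-wise significance level for the Tukey contrasts.
#' @param letters Compute the Tukey contrasts and compact letter display?
#'   Disable when only the omnibus F-test is needed (e.g. in simulation
#'   loops).
#' @return A list: `F`, `p` (condition effect), `letters` (named character,
#'   one per condition), `tukey` (matrix of pairwise estimates and adjusted
#'   p-values), `fit` (the `aov` object).
#' @export
rbd_anova_tukey <- function(values, condition, block, alpha = 0.05,
                            letters = TRUE) {
  d <- data.frame(value = values, condition = factor(condition),
                  block = factor(block))
  stopifnot(nrow(d) >= 4, all(is.finite(d$value)))
  tab <- table(d$condition, d$block)
  if (any(tab == 0)) {
    stop("incomplete blocks: every condition must appear in every block",
         call. = FALSE)
  }
  if (sd(d$value) < .Machine$double.eps^0.5) {
    lev <- levels(d$condition)
    return(list(F = 0, p = 1,
                letters = setNames(rep("a", length(lev)), lev),
                tukey = NULL, fit = NULL))
  }
  fit <- aov(value ~ condition + block, data = d)
  an <- summary(fit)[[1]]
  out <- list(F = an["condition", "F value"], p = an["condition", "Pr(>F)"],
              letters = NULL, tukey = NULL, fit = fit)
  if (letters) {
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Tukey"))
    cld_out <- multcomp::cld(glht_fit, level = alpha)
    tk <- summary(glht_fit)
    out$tukey <- cbind(estimate = tk$test$coefficients, p_adj = tk$test$pvalues)
    out$letters <- cld_out$mcletters$Letters
  }
  out
}
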