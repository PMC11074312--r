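test_that("housekeeping normalization matches hand arithmetic", {
  # target N0 = 8 with GAPDH 4 and PGK1 16: geometric mean 8, log2 ratio 0
  tab <- tibble::tibble(
    gene = c("Nanog", "GAPDH", "PGK1"),
    replicate = 1L, condition = "ctrl",
    N0 = c(8, 4, 16)
  )
  out <- normalize_expression(tab, control_condition = "ctrl")
  expect_equal(out$rel_log2_expr, 0)

  # control replicates with equal values relativize to exactly zero
  tab2 <- tibble::tibble(
    gene = rep(c("Nanog", "GAPDH", "PGK1"), 3),
    replicate = rep(1:3, each = 3),
    condition = "2i+LIF",
    N0 = rep(c(10, 5, 20), 3)
  )
  out2 <- normalize_expression(tab2, control_condition = "2i+LIF")
  expect_true(all(out2$rel_log2_expr == 0))
})

test_that("normalization equals an independent spreadsheet-style oracle", {
  genes <- c("Nanog", "Sox3")
  conds <- c("2i+LIF", "24h", "48h")
  withr::with_seed(12, {
    grid <- expand.grid(gene = c(genes, "GAPDH", "PGK1"),
                        replicate = 1:3, condition = conds,
                        stringsAsFactors = FALSE)
    grid$N0 <- exp(runif(nrow(grid), 0, 3))
  })
  got <- normalize_expression(tibble::as_tibble(grid),
                              control_condition = "2i+LIF")

  # oracle: explicit loops, no shared code with the implementation
  oracle <- function(g, rep_, cond) {
    pick <- function(gene, r, cc) {
      grid$N0[grid$gene == gene & grid$replicate == r & grid$condition == cc]
    }
    val <- function(r, cc) {
      log2(pick(g, r, cc) / sqrt(pick("GAPDH", r, cc) * pick("PGK1", r, cc)))
    }
    ctrl <- mean(c(val(1, "2i+LIF"), val(2, "2i+LIF"), val(3, "2i+LIF")))
    val(rep_, cond) - ctrl
  }
  for (i in seq_len(nrow(got))) {
    expect_equal(got$rel_log2_expr[i],
                 oracle(got$gene[i], got$replicate[i], got$condition[i]),
                 tolerance = 1e-12)
  }
})

test_that("normalization is invariant to per-sample scale factors", {
  tab <- generate_qpcr_table(c("Nanog"), c("ctrl", "treated"), n_blocks = 3,
                             effects = matrix(c(0, 2), 1), seed = 5)
  base <- normalize_expression(tab, control_condition = "ctrl")
  scaled <- tab
  # arbitrary multiplicative factor per (replicate, condition) sample
  f <- setNames(c(2, 0.5, 10, 1, 3, 7),
                paste(rep(1:3, 2), rep(c("ctrl", "treated"), each = 3)))
  scaled$N0 <- unname(scaled$N0 * f[paste(scaled$replicate, scaled$condition)])
  out <- normalize_expression(scaled, control_condition = "ctrl")
  expect_equal(out$rel_log2_expr, base$rel_log2_expr, tolerance = 1e-12)
})

test_that("normalization rejects bad N0 and incomplete housekeeping", {
  bad <- tibble::tibble(gene = c("Nanog", "GAPDH", "PGK1"), replicate = 1L,
                        condition = "ctrl", N0 = c(-1, 2, 3))
  expect_error(normalize_expression(bad, control_condition = "ctrl"),
               "positive")
  missing_hk <- tibble::tibble(gene = c("Nanog", "GAPDH"), replicate = 1L,
                               condition = "ctrl", N0 = c(1, 2))
  expect_error(normalize_expression(missing_hk, control_condition = "ctrl"),
               "PGK1")
})

test_that("randomized-block ANOVA separates clear effects with letters", {
  # identical data in every condition: no effect, one shared letter
  flat <- rbd_anova_tukey(rep(1, 9), rep(c("a", "b", "c"), each = 3),
                          rep(1:3, 3))
  expect_equal(flat$F, 0)
  expect_equal(length(unique(flat$letters)), 1)

  # two conditions ten within-group sds apart must get distinct letters
  withr::with_seed(7, {
    y <- c(rnorm(3, 0, 1), rnorm(3, 10, 1))
  })
  two <- rbd_anova_tukey(y, rep(c("lo", "hi"), each = 3), rep(1:3, 2))
  expect_lt(two$p, 0.05)
  expect_false(two$letters["lo"] == two$letters["hi"])

  expect_error(
    rbd_anova_tukey(1:5, c("a", "a", "b", "b", "b"), c(1, 2, 1, 2, 3)),
    "incomplete")
})

test_that("letter display agrees with an exhaustive pairwise Tukey oracle", {
  withr::with_seed(15, {
    cond <- rep(c("a", "b", "c"), each = 4)
    block <- rep(1:4, 3)
    y <- c(rnorm(4, 0), rnorm(4, 0.3), rnorm(4, 6)) + 0.2 * block
  })
  fit <- rbd_anova_tukey(y, cond, block)
  # oracle: stats::TukeyHSD on the same additive model
  tk <- stats::TukeyHSD(aov(y ~ factor(cond) + factor(block)))$`factor(cond)`
  share_letter <- function(a, b) {
    la <- strsplit(fit$letters[a], "")[[1]]
    lb <- strsplit(fit$letters[b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (pair in rownames(tk)) {
    ab <- strsplit(pair, "-")[[1]]
    expect_equal(share_letter(ab[1], ab[2]), tk[pair, "p adj"] >= 0.05)
  }
})
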