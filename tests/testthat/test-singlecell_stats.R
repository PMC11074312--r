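test_that("fold normalization is a plain ratio with a guarded background", {
  expect_equal(fold_over_background(c(50, 200), 50), c(1, 4))
  expect_error(fold_over_background(10, 0), "background")
  expect_error(fold_over_background(10, -3), "background")
})

test_that("threshold classification is inclusive at the cutoff", {
  st <- classify_on_off(c(1.9, 2.0, 2.1), "threshold", cutoff = 2)
  expect_equal(st$state, c(FALSE, TRUE, TRUE))
})

test_that("degenerate input yields a single-population verdict, not a crash", {
  st <- classify_on_off(rep(5, 30), "gmm2_log")
  expect_true(st$degenerate)
  expect_true(is.na(st$D))
  expect_equal(length(unique(st$state)), 1)
})

test_that("the log-Gaussian mixture recovers a well-separated ON fraction", {
  withr::with_seed(11, {
    vals <- exp(c(rnorm(500, 0, 0.2), rnorm(500, 2, 0.2)))
  })
  st <- classify_on_off(vals, "gmm2_log")
  expect_lt(abs(mean(st$state) - 0.5), 0.05)
  # closed-form separation: |0 - 2| / 0.2 = 10
  expect_gt(st$D, 4)
})

test_that("dose-response bins partition the cells and flag empty bins", {
  fold <- c(0.8, 1.0, 1.7, 2.5, 3.0, 6.0)
  on <- rep(TRUE, 6)
  curve <- dose_response(fold, on)
  expect_equal(sum(curve$n_cells), 6)
  expect_true(all(curve$fraction_negative[curve$n_cells > 0] == 0))

  empty <- dose_response(c(0.9, 1.1), c(TRUE, FALSE))
  expect_true(is.na(empty$fraction_negative[empty$bin == ">=4x"]))
  expect_equal(empty$n_cells[empty$bin == ">=4x"], 0)
})

test_that("binned response-negative fractions match the Hill-integrated truth", {
  ep <- expression_params(f_half = 2, h = 6, seed = 5)
  tab <- generate_cell_table(5000, ep)
  curve <- dose_response(tab$true_fold, tab$response_on)
  bins <- fold_bins()
  idx <- cut(tab$true_fold, bins$edges, labels = bins$labels, right = FALSE)
  for (b in bins$labels) {
    n <- curve$n_cells[curve$bin == b]
    if (n < 50) next
    truth <- 1 - mean(tab$p_response_on[idx == b])
    expect_lt(abs(curve$fraction_negative[curve$bin == b] - truth), 0.05)
  }
  # a monotone repressive link gives a non-decreasing negative fraction
  occ <- curve[curve$n_cells > 0, ]
  expect_true(all(diff(occ$fraction_negative) >= -1e-12))
})

test_that("channel correlation matches exact and Fisher-z expectations", {
  a <- c(1, 2, 3, 4, 5)
  lin <- correlate_channels(a, 2 * a, log = FALSE)
  expect_equal(lin$r, 1)
  expect_equal(lin$slope, 2)
  neg <- correlate_channels(a, -a + 10, log = FALSE)
  expect_equal(neg$r, -1)

  expect_true(correlate_channels(a, rep(2, 5), log = FALSE)$degenerate)

  withr::with_seed(13, {
    z1 <- rnorm(1000)
    z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(1000)
  })
  got <- correlate_channels(exp(z1), exp(z2), log = TRUE)
  # Fisher 99% CI around rho = 0.9 at n = 1000
  zeta <- atanh(got$r)
  half <- qnorm(0.995) / sqrt(1000 - 3)
  expect_true(atanh(0.9) > zeta - half && atanh(0.9) < zeta + half)
})

test_that("fraction positive covers the trivial and calibrated cases", {
  expect_equal(fraction_positive(c(5, 6, 7), "threshold", cutoff = 2)$fraction, 1)
  expect_equal(fraction_positive(c(0.5, 0.6), "threshold", cutoff = 2)$fraction, 0)
  expect_error(fraction_positive(numeric(0), "threshold"), "empty")

  withr::with_seed(19, {
    on <- runif(2000) < 0.7
    vals <- ifelse(on, exp(rnorm(2000, 2, 0.2)), exp(rnorm(2000, 0, 0.2)))
  })
  est <- fraction_positive(vals, "gmm2_log")
  half <- qnorm(0.995) * sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(est$fraction - 0.7), half + 0.01)
})

test_that("equal-count gating balances the three gates with stable ties", {
  withr::with_seed(23, v300 <- runif(300))
  g <- gate_equal_thirds(v300)
  expect_equal(as.vector(table(g)), c(100, 100, 100))
  # Low really holds the smallest values
  expect_lt(max(v300[g == "Low"]), min(v300[g == "High"]))

  withr::with_seed(23, v301 <- runif(301))
  g301 <- gate_equal_thirds(v301)
  expect_equal(as.vector(table(g301)), c(101, 100, 100))

  g_tie <- gate_equal_thirds(rep(1, 7))
  expect_equal(as.vector(table(g_tie)), c(3, 2, 2))
  # stable input order: the first cells land in Low
  expect_equal(as.character(g_tie[1:3]), rep("Low", 3))
})
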