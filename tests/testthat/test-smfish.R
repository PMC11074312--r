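test_that("the LoG filter behaves as a linear blob detector", {
  const <- matrix(7, 64, 64)
  expect_lt(max(abs(log_filter(const, 2))), 1e-9)

  # Gaussian blob of sd s filtered at sigma = s peaks at the blob center
  s <- 3
  blob <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
  blob <- exp(-blob / (2 * s^2))
  resp <- log_filter(blob, s)
  peak <- which(resp == max(resp), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(32, 32))), 1)

  withr::with_seed(4, img <- matrix(runif(64 * 64), 64))
  expect_equal(log_filter(3.5 * img, 2), 3.5 * log_filter(img, 2),
               tolerance = 1e-9)

  expect_error(log_filter(const, 20), "quarter")
})

test_that("maximum-intensity projection equals the per-plane oracle", {
  withr::with_seed(6, stack <- array(runif(20 * 20 * 5), c(20, 20, 5)))
  mip <- max_intensity_projection(stack)
  oracle <- matrix(0, 20, 20)
  for (r in 1:20) for (c in 1:20) oracle[r, c] <- max(stack[r, c, ])
  expect_identical(mip, oracle)

  one <- array(0, c(10, 10, 4))
  one[, , 3] <- matrix(runif(100), 10)
  expect_identical(max_intensity_projection(one), one[, , 3])

  expect_warning(again <- max_intensity_projection(mip), "z dimension")
  expect_identical(again, mip)
})

test_that("spot detection handles blank input and suppresses near-duplicates", {
  withr::with_seed(3, blank <- matrix(rnorm(64 * 64), 64))
  filt <- log_filter(blank, 1.5)
  expect_equal(nrow(detect_spots(filt, "absolute", value = max(filt) + 1)), 0)

  img <- matrix(0, 40, 40)
  img[20, 20] <- 100; img[20, 21] <- 90   # 1 px apart
  filt2 <- log_filter(img, 1.5)
  calls <- detect_spots(filt2, "absolute", value = 1, min_separation_px = 3)
  expect_equal(nrow(calls), 1)
})

test_that("detection recovers synthetic spots at high SNR", {
  d <- disk_labels(5, 6, radius = 18, spacing = 55, margin = 35)
  sp <- spot_params(n_spots_per_cell = 20, count_model = "fixed",
                    amplitude = 100, noise_sd = 10, seed = 2)
  out <- generate_spot_stack(d$labels, sp)
  filt <- log_filter(out$stack, sp$spot_sigma_px)
  calls <- detect_spots(filt, "k_sigma", k = 5, min_separation_px = 3)
  m <- match_spots(calls$x, calls$y, out$truth$x, out$truth$y, radius = 2)
  expect_gte(m$tp / m$n_true, 0.95)   # recall
  expect_gte(m$tp / m$n_det, 0.95)    # precision

  # per-cell counts: within +/-1 of truth for >= 90% of cells
  counts <- assign_spots_to_cells(calls, d$labels)$counts
  truth_counts <- as.data.frame(table(out$truth$cell))
  got <- counts$n_spots[match(truth_counts$Var1, counts$cell)]
  expect_gte(mean(abs(got - truth_counts$Freq) <= 1), 0.9)
})

test_that("detection count is monotone non-increasing in the threshold", {
  d <- disk_labels(2, 2, radius = 18, spacing = 55, margin = 35)
  sp <- spot_params(n_spots_per_cell = 12, count_model = "fixed", seed = 5)
  out <- generate_spot_stack(d$labels, sp)
  filt <- max_intensity_projection(log_filter(out$stack, sp$spot_sigma_px))
  thresholds <- quantile(filt, c(0.5, 0.9, 0.99, 0.999))
  n_calls <- vapply(thresholds, function(t) {
    nrow(detect_spots(filt, "absolute", value = t))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("spot-to-cell assignment conserves detections and flags background", {
  labels <- matrix(0L, 30, 30)
  labels[10:20, 10:20] <- 1L
  spots <- tibble::tibble(x = c(15, 15.4, 2), y = c(15, 16, 2),
                          intensity = c(5, 4, 3))
  res <- assign_spots_to_cells(spots, labels)
  expect_equal(res$counts$n_spots[res$counts$cell == 1], 2)
  expect_equal(res$counts$n_spots[res$counts$cell == 0], 1)
  expect_equal(sum(res$counts$n_spots), nrow(spots))

  expect_error(
    assign_spots_to_cells(tibble::tibble(x = 99, y = 2), labels),
    "outside")
})

test_that("driver-high cells carry fewer transcripts than driver-low cells", {
  # couple per-cell spot abundance to a simulated protein state, as when the
  # repressor is high the response transcript is lost
  d <- disk_labels(4, 5, radius = 18, spacing = 55, margin = 35)
  n_cells <- 20
  withr::with_seed(31, driver_high <- runif(n_cells) < 0.5)
  means <- ifelse(driver_high, 1, 15)
  sp <- spot_params(n_spots_per_cell = means, count_model = "poisson", seed = 8)
  out <- generate_spot_stack(d$labels, sp)
  filt <- log_filter(out$stack, sp$spot_sigma_px)
  calls <- detect_spots(filt, "k_sigma", k = 5, min_separation_px = 3)
  counts <- assign_spots_to_cells(calls, d$labels)$counts
  per_cell <- counts$n_spots[match(seq_len(n_cells), counts$cell)]
  expect_lt(mean(per_cell[driver_high]), mean(per_cell[!driver_high]))
})
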