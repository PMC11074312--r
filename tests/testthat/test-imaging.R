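test_that("percentile background subtraction is exact on constant images", {
  img <- matrix(37, 50, 50)
  out <- subtract_background(img, "percentile", p = 25)
  expect_equal(out$background, 37)
  expect_true(all(out$image == 0))

  # constant plus one bright disk: interior recovers original minus background
  img2 <- matrix(20, 80, 80)
  for (r in 1:80) for (c in 1:80) {
    if ((r - 40)^2 + (c - 40)^2 <= 10^2) img2[r, c] <- 220
  }
  out2 <- subtract_background(img2, "percentile", p = 25)
  expect_equal(out2$background, 20)
  expect_equal(out2$image[40, 40], 200)

  expect_error(subtract_background(img, "percentile", p = 0), "percentile")
  expect_error(subtract_background(img, "rolling_ball", radius_px = 100),
               "radius")
})

test_that("percentile background lands near the generator's background level", {
  sim <- generate_colony_image(
    colony_params(4, 15, image_shape_px = c(300, 300), seed = 13),
    expression_params(seed = 13))
  bg <- subtract_background(sim$image$channels$mCherry, "percentile",
                            p = 25)$background
  expect_lt(abs(bg - 100) / 100, 0.05)
})

test_that("segmentation handles empty images and splits touching disks", {
  expect_equal(max(segment_nuclei(matrix(0, 60, 60))), 0)

  # two disks overlapping by 20% of the radius must be split in two
  img <- matrix(10, 100, 100)
  r <- 12
  centers <- list(c(50, 40), c(50, 40 + 1.8 * r))
  for (ctr in centers) {
    for (rr in 1:100) for (cc in 1:100) {
      if ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2) img[rr, cc] <- 500
    }
  }
  labels <- segment_nuclei(img)
  expect_equal(max(labels), 2)
})

test_that("segmentation is translation-equivariant on a synthetic field", {
  sim <- generate_colony_image(
    colony_params(3, 10, image_shape_px = c(220, 220), seed = 31),
    expression_params(seed = 31))
  dapi <- sim$image$channels$DAPI
  shift <- 17L
  big <- matrix(median(dapi), 220 + shift, 220 + shift)
  big[(shift + 1):(220 + shift), (shift + 1):(220 + shift)] <- dapi
  base <- measure_nuclei(segment_nuclei(dapi), list(I = dapi))
  moved <- measure_nuclei(segment_nuclei(big), list(I = big))
  expect_equal(nrow(moved), nrow(base))
  ord_b <- order(base$x, base$y); ord_m <- order(moved$x, moved$y)
  expect_lt(max(abs(moved$x[ord_m] - (base$x[ord_b] + shift))), 0.5)
  expect_lt(max(abs(moved$y[ord_m] - (base$y[ord_b] + shift))), 0.5)
})

test_that("per-nucleus means equal simple hand values and the pixel-loop oracle", {
  labels <- matrix(0L, 10, 10)
  labels[3:6, 3:6] <- 1L
  chan <- matrix(100, 10, 10)
  out <- measure_nuclei(labels, list(marker = chan))
  expect_equal(out$marker, 100)

  labels2 <- matrix(0L, 4, 4)
  labels2[1, 1:4] <- 1L
  chan2 <- matrix(0, 4, 4); chan2[1, 3:4] <- 100
  expect_equal(measure_nuclei(labels2, list(m = chan2))$m, 50)

  # 50 random rectangular masks vs explicit per-pixel loop
  withr::with_seed(42, {
    labels3 <- matrix(0L, 60, 60)
    for (k in 1:50) {
      r0 <- sample(1:55, 1); c0 <- sample(1:55, 1)
      labels3[r0:(r0 + 4), c0:(c0 + 4)] <- k  # later masks overwrite earlier
    }
    chan3 <- matrix(runif(3600, 0, 1000), 60, 60)
  })
  got <- measure_nuclei(labels3, list(v = chan3))
  want <- measure_oracle(labels3, chan3)
  expect_equal(got$label, want$label)
  expect_equal(got$v, want$mean, tolerance = 1e-9)

  expect_error(measure_nuclei(labels3, list(v = chan3[1:30, ])), "shape")
})

test_that("measurement is linear in intensity and exact on ground-truth masks", {
  d <- disk_labels(2, 3, radius = 8)
  withr::with_seed(8, chan <- matrix(runif(nrow(d$labels) * ncol(d$labels)),
                                     nrow(d$labels)))
  base <- measure_nuclei(d$labels, list(v = chan))
  scaled <- measure_nuclei(d$labels, list(v = 3 * chan + 7))
  expect_equal(scaled$v, 3 * base$v + 7, tolerance = 1e-12)

  # noiseless hard-disk channel measured on the true label mask is exact
  vals <- c(10, 20, 30, 40, 50, 60)
  noiseless <- matrix(0, nrow(d$labels), ncol(d$labels))
  for (k in 1:6) noiseless[d$labels == k] <- vals[k]
  got <- measure_nuclei(d$labels, list(v = noiseless))
  expect_equal(got$v, vals)
  expect_equal(got$x, d$centers$x, tolerance = 1e-9)
  expect_equal(got$y, d$centers$y, tolerance = 1e-9)
})
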