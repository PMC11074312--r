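test_that("empty and bookkeeping cases of the colony generator", {
  ep <- expression_params(seed = 3)

  empty <- generate_colony_image(
    colony_params(n_colonies = 0, image_shape_px = c(64, 64), seed = 3), ep)
  expect_equal(nrow(empty$truth), 0)
  # channels are background plus noise only: mean near the background level
  expect_lt(abs(mean(empty$image$channels$mCherry) - 100), 5)

  sim <- generate_colony_image(
    colony_params(5, 20, packing_mode = "tight", seed = 7), ep)
  expect_equal(nrow(sim$truth), 100)
  expect_setequal(names(sim$image$channels), c("DAPI", "mCherry", "NANOG"))
})

test_that("identical parameters and seed reproduce byte-identical output", {
  cp <- colony_params(3, 12, image_shape_px = c(256, 256), seed = 21)
  ep <- expression_params(seed = 21)
  a <- generate_colony_image(cp, ep)
  b <- generate_colony_image(cp, ep)
  expect_identical(a$truth, b$truth)
  expect_identical(a$image$channels, b$image$channels)

  ta <- generate_cell_table(500, ep)
  tb <- generate_cell_table(500, ep)
  expect_identical(ta, tb)
})

test_that("spread mode packs nuclei less densely than tight mode", {
  ep <- expression_params(seed = 5)
  tight <- generate_colony_image(
    colony_params(5, 20, packing_mode = "tight", seed = 5), ep)
  spread <- generate_colony_image(
    colony_params(5, 20, packing_mode = "spread", seed = 5), ep)
  nn_t <- nearest_neighbor_distances(tight$truth$x, tight$truth$y)
  nn_s <- nearest_neighbor_distances(spread$truth$x, spread$truth$y)
  expect_lt(median(nn_t), median(nn_s))
})

test_that("an over-packed field fails with the packing constraint named", {
  expect_error(
    generate_colony_image(
      colony_params(4, 60, image_shape_px = c(96, 96), seed = 1),
      expression_params(seed = 1)),
    "too small"
  )
})

test_that("cell-table mixture respects the driver fraction and step-limit Hill", {
  ep0 <- expression_params(fraction_driver_positive = 0, seed = 2)
  tab <- generate_cell_table(500, ep0)
  expect_false(any(tab$driver_positive))
  # all driver intensities from the OFF component: folds near 1
  expect_lt(max(tab$true_fold), 2)

  # h -> infinity turns the Hill link into a step at f_half
  expect_gt(hill_on_probability(1.5, f_half = 2, h = 50), 0.999)
  expect_lt(hill_on_probability(3, f_half = 2, h = 50), 0.001)
})

test_that("empirical ON fractions track the Hill link within binomial error", {
  ep <- expression_params(f_half = 2, h = 4, seed = 1)
  tab <- generate_cell_table(10000, ep)
  bins <- cut(tab$true_fold, c(0, 1.5, 2, 4, Inf), right = FALSE)
  for (b in levels(bins)) {
    in_b <- bins == b
    n <- sum(in_b)
    if (n < 30) next
    p_hat <- mean(tab$response_on[in_b])
    p_true <- mean(tab$p_response_on[in_b])
    # binomial 99% envelope around the Hill-integrated truth
    half <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), half + 1e-9)
  }
})

test_that("gene universe construction is recovered exactly by the assignment rule", {
  uni <- generate_gene_universe(1000, 0.137, seed = 3)
  expect_equal(sum(uni$genes$has_peak), 137)
  assigned <- assign_peaks_to_genes(uni$peaks, uni$genes)
  expect_identical(assigned$has_peak, uni$genes$has_peak)

  all_on <- generate_gene_universe(50, 1, genome_length = 5e6, seed = 4)
  expect_true(all(assign_peaks_to_genes(all_on$peaks, all_on$genes)$has_peak))

  none <- generate_gene_universe(50, 0, genome_length = 5e6, seed = 4)
  expect_equal(nrow(none$peaks), 0)
  expect_false(any(assign_peaks_to_genes(none$peaks, none$genes)$has_peak))

  expect_error(generate_gene_universe(1000, 0.1, genome_length = 1e6),
               "too short")
})

test_that("spot stacks conserve counts and record true coordinates", {
  d <- disk_labels(1, 1, radius = 20)
  sp0 <- spot_params(n_spots_per_cell = 0, count_model = "fixed", seed = 2)
  out0 <- generate_spot_stack(d$labels, sp0)
  expect_equal(nrow(out0$truth), 0)

  sp20 <- spot_params(n_spots_per_cell = 20, count_model = "fixed", seed = 2)
  out20 <- generate_spot_stack(d$labels, sp20)
  expect_equal(nrow(out20$truth), 20)

  d30 <- disk_labels(5, 6, radius = 18, spacing = 55, margin = 35)
  spp <- spot_params(n_spots_per_cell = 15, count_model = "poisson", seed = 9)
  outp <- generate_spot_stack(d30$labels, spp)
  counts <- table(outp$truth$cell)
  expect_equal(sum(counts), nrow(outp$truth))
  # spots lie inside their assigned cell's mask
  lab_at <- d30$labels[cbind(round(outp$truth$y), round(outp$truth$x))]
  expect_true(all(lab_at == outp$truth$cell))
})
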