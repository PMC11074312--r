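#' Parameters for synthetic colony geometry
#'
#' Describes how nuclei are laid out in a simulated field of view. Two packing
#' modes are supported: `"tight"` mimics compact, dome-like colonies in which
#' nuclei sit close to the minimum center-to-center separation, while
#' `"spread"` mimics flattened, differentiating colonies with looser packing
#' plus a fraction of colony-detached single cells scattered across the field.
#'
#' @param n_colonies Number of colonies to place.
#' @param nuclei_per_colony Mean number of nuclei per colony.
#' @param nuclei_dispersion Standard deviation of the per-colony nucleus
#'   count; `0` (the default) gives exactly `nuclei_per_colony` nuclei in
#'   every colony.
#' @param nucleus_radius_px,nucleus_radius_sd Mean and standard deviation of
#'   the nuclear radius, in pixels.
#' @param packing_mode `"tight"` or `"spread"` (see Details).
#' @param image_shape_px Integer vector `c(height, width)` of the image.
#' @param detached_fraction In `"spread"` mode, the fraction of nuclei placed
#'   as colony-detached singletons anywhere in the field. Ignored in
#'   `"tight"` mode.
#' @param max_overlap_fraction Maximum allowed overlap between two nuclei,
#'   as a fraction of the mean radius; the minimum center separation is
#'   `2 * nucleus_radius_px * (1 - max_overlap_fraction)`.
#' @param seed Integer seed; every realization with the same parameters and
#'   seed is identical.
#'
#' @return An object of class `colony_params`.
#' @seealso [generate_colony_image()]
#' @export
colony_params <- function(n_colonies = 5,
                          nuclei_per_colony = 20,
                          nuclei_dispersion = 0,
                          nucleus_radius_px = 8,
                          nucleus_radius_sd = 0.8,
                          packing_mode = c("tight", "spread"),
                          image_shape_px = c(512L, 512L),
                          detached_fraction = 0.15,
                          max_overlap_fraction = 0.05,
                          seed = 1L) {
  packing_mode <- match.arg(packing_mode)
  stopifnot(
    n_colonies >= 0, nuclei_per_colony >= 1, nuclei_dispersion >= 0,
    nucleus_radius_px > 0, nucleus_radius_sd >= 0,
    length(image_shape_px) == 2, all(image_shape_px >= 16),
    detached_fraction >= 0, detached_fraction <= 1,
    max_overlap_fraction >= 0, max_overlap_fraction < 1,
    is.numeric(seed), length(seed) == 1, is.finite(seed)
  )
  structure(
    list(
      n_colonies = as.integer(n_colonies),
      nuclei_per_colony = nuclei_per_colony,
      nuclei_dispersion = nuclei_dispersion,
      nucleus_radius_px = nucleus_radius_px,
      nucleus_radius_sd = nucleus_radius_sd,
      packing_mode = packing_mode,
      image_shape_px = as.integer(image_shape_px),
      detached_fraction = detached_fraction,
      max_overlap_fraction = max_overlap_fraction,
      seed = as.integer(seed)
    ),
    class = "colony_params"
  )
}

#' Parameters for per-nucleus expression levels
#'
#' Each channel has an ON and an OFF log-normal intensity component. The
#' driver channel (an inducible reporter such as mCherry) is ON in a fixed
#' fraction of cells; the response channel (e.g. NANOG) is ON with a
#' probability that decreases with the driver's fold over background through
#' a repressive Hill link:
#' \deqn{P(\mathrm{ON} \mid f) = \frac{1}{1 + (f / f_{1/2})^h}}
#' where `f` is the driver fold over background. Driver-negative cells carry
#' background-level signal, so their fold is close to 1 and the response is
#' almost always ON; strongly driver-positive cells almost always switch the
#' response OFF. This encodes the bistable, dose-dependent repression the
#' analysis stages are designed to recover.
#'
#' @param channels Channel names; must include `"DAPI"`, the driver and the
#'   response channel.
#' @param driver,response Names of the driver and response channels.
#' @param background_level Uniform image background intensity (counts).
#' @param on_meanlog,on_sdlog,off_meanlog,off_sdlog Named numeric vectors of
#'   log-normal parameters per channel for the ON and OFF states. For every
#'   channel `on_meanlog` must exceed `off_meanlog`.
#' @param f_half Driver fold over background at which the response is ON with
#'   probability one half.
#' @param h Hill steepness (unitless, > 0); large values approach a hard
#'   threshold at `f_half`.
#' @param fraction_driver_positive Fraction of cells in which the driver is ON.
#' @param read_noise_sd Gaussian read-noise standard deviation added on top
#'   of Poisson shot noise when rendering images.
#' @param seed Integer seed used by the generators consuming these parameters.
#'
#' @return An object of class `expression_params`.
#' @seealso [generate_cell_table()], [generate_colony_image()]
#' @export
expression_params <- function(channels = c("DAPI", "mCherry", "NANOG"),
                              driver = "mCherry",
                              response = "NANOG",
                              background_level = 100,
                              on_meanlog = c(DAPI = log(1500), mCherry = log(600), NANOG = log(900)),
                              on_sdlog = c(DAPI = 0.15, mCherry = 0.9, NANOG = 0.3),
                              off_meanlog = c(DAPI = log(1200), mCherry = log(100), NANOG = log(105)),
                              off_sdlog = c(DAPI = 0.15, mCherry = 0.12, NANOG = 0.3),
                              f_half = 2,
                              h = 6,
                              fraction_driver_positive = 0.75,
                              read_noise_sd = 3,
                              seed = 1L) {
  stopifnot(
    is.character(channels), length(channels) >= 2,
    driver %in% channels, response %in% channels,
    all(c("DAPI") %in% channels),
    is.finite(background_level), background_level > 0,
    is.finite(f_half), f_half > 0, is.finite(h), h > 0,
    fraction_driver_positive >= 0, fraction_driver_positive <= 1,
    read_noise_sd >= 0,
    is.numeric(seed), length(seed) == 1, is.finite(seed)
  )
  for (p in list(on_meanlog, on_sdlog, off_meanlog, off_sdlog)) {
    if (!all(channels %in% names(p)) || !all(is.finite(p[channels]))) {
      stop("log-normal parameters must be finite and named for every channel",
           call. = FALSE)
    }
  }
  if (!all(on_meanlog[channels] > off_meanlog[channels])) {
    stop("on_meanlog must exceed off_meanlog for every channel", call. = FALSE)
  }
  structure(
    list(
      channels = channels, driver = driver, response = response,
      background_level = background_level,
      on_meanlog = on_meanlog[channels], on_sdlog = on_sdlog[channels],
      off_meanlog = off_meanlog[channels], off_sdlog = off_sdlog[channels],
      f_half = f_half, h = h,
      fraction_driver_positive = fraction_driver_positive,
      read_noise_sd = read_noise_sd,
      seed = as.integer(seed)
    ),
    class = "expression_params"
  )
}

#' Repressive Hill link between driver fold and response ON probability
#'
#' @param fold Driver fold over background (positive).
#' @param f_half Fold at half-maximal repression.
#' @param h Hill steepness.
#' @return `P(response ON | fold)`, decreasing in `fold`.
#' @export
hill_on_probability <- function(fold, f_half, h) {
  stopifnot(f_half > 0, h > 0)
  1 / (1 + (pmax(fold, .Machine$double.eps) / f_half)^h)
}

# Sample per-cell true expression states and intensities for all channels.
# Returns a tibble with one row per cell.
sample_expression <- function(n, expr) {
  bg <- expr$background_level
  driver_on <- runif(n) < expr$fraction_driver_positive
  intens <- function(ch, on) {
    ifelse(on,
           rlnorm(length(on), expr$on_meanlog[[ch]], expr$on_sdlog[[ch]]),
           rlnorm(length(on), expr$off_meanlog[[ch]], expr$off_sdlog[[ch]]))
  }
  driver_int <- intens(expr$driver, driver_on)
  fold <- driver_int / bg
  p_on <- hill_on_probability(fold, expr$f_half, expr$h)
  response_on <- runif(n) < p_on
  response_int <- intens(expr$response, response_on)
  out <- tibble::tibble(
    driver_positive = driver_on,
    true_fold = fold,
    p_response_on = p_on,
    response_on = response_on
  )
  for (ch in expr$channels) {
    vals <- if (ch == expr$driver) driver_int
            else if (ch == expr$response) response_int
            else intens(ch, rep(TRUE, n))  # constitutive channels (DAPI)
    out[[ch]] <- vals
  }
  out
}

# Rejection-sample nucleus centers obeying a minimum pairwise separation.
# Returns a data.frame with columns x, y, colony.
place_nuclei <- function(colony) {
  h <- colony$image_shape_px[1]; w <- colony$image_shape_px[2]
  r <- colony$nucleus_radius_px
  min_sep <- 2 * r * (1 - colony$max_overlap_fraction)
  counts <- if (colony$nuclei_dispersion == 0) {
    rep(round(colony$nuclei_per_colony), colony$n_colonies)
  } else {
    pmax(1L, round(rnorm(colony$n_colonies, colony$nuclei_per_colony,
                         colony$nuclei_dispersion)))
  }
  if (colony$n_colonies == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), colony = integer(0)))
  }
  # colony disk radius scales with sqrt(count); looser in spread mode
  scale <- if (colony$packing_mode == "tight") 0.85 else 2.2
  xs <- numeric(0); ys <- numeric(0); col_id <- integer(0)
  margin <- r + 2
  add_point <- function(cx, cy, radius, label) {
    # one rejection-sampled center within a disk (or the whole field)
    for (attempt in seq_len(4000)) {
      if (is.null(radius)) {
        px <- runif(1, margin, w - margin); py <- runif(1, margin, h - margin)
      } else {
        ang <- runif(1, 0, 2 * pi); rad <- radius * sqrt(runif(1))
        px <- cx + rad * cos(ang); py <- cy + rad * sin(ang)
        if (px < margin || px > w - margin || py < margin || py > h - margin) next
      }
      if (length(xs) == 0 ||
          min((xs - px)^2 + (ys - py)^2) >= min_sep^2) {
        xs <<- c(xs, px); ys <<- c(ys, py); col_id <<- c(col_id, label)
        return(invisible(TRUE))
      }
    }
    stop("image too small for the requested nuclei at minimum separation ",
         signif(min_sep, 3), " px (packing constraint)", call. = FALSE)
  }
  n_det <- if (colony$packing_mode == "spread") {
    vapply(counts, function(n) rbinom(1, n, colony$detached_fraction), integer(1))
  } else rep(0L, colony$n_colonies)
  radii <- scale * min_sep * sqrt(pmax(counts - n_det, 1))
  if (any(2 * (radii + margin) > min(h, w))) {
    stop("image too small for a colony of radius ", round(max(radii)),
         " px at the requested packing constraint", call. = FALSE)
  }
  # colony centers kept apart so tight colonies stay distinct entities;
  # spread colonies are allowed to interleave freely
  sep_factor <- if (colony$packing_mode == "tight") 0.95 else 0
  ccx <- numeric(0); ccy <- numeric(0)
  for (k in seq_len(colony$n_colonies)) {
    ok <- FALSE
    for (attempt in seq_len(2000)) {
      cx <- runif(1, radii[k] + margin, w - radii[k] - margin)
      cy <- runif(1, radii[k] + margin, h - radii[k] - margin)
      if (length(ccx) == 0 ||
          all(sqrt((ccx - cx)^2 + (ccy - cy)^2) >=
                sep_factor * (radii[seq_along(ccx)] + radii[k]))) {
        ccx <- c(ccx, cx); ccy <- c(ccy, cy); ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("image too small to place ", colony$n_colonies,
           " colonies at the requested packing constraint", call. = FALSE)
    }
  }
  for (k in seq_len(colony$n_colonies)) {
    for (i in seq_len(counts[k] - n_det[k])) add_point(ccx[k], ccy[k], radii[k], k)
    for (i in seq_len(n_det[k])) add_point(NA, NA, NULL, k)
  }
  data.frame(x = xs, y = ys, colony = col_id)
}

# Render one channel: nuclei as hard disks at their true intensity over a
# uniform background, with a 1-px Gaussian edge blur, Poisson shot noise and
# additive Gaussian read noise.
render_channel <- function(truth, values, shape, background, read_sd,
                           edge_sigma = 1) {
  h <- shape[1]; w <- shape[2]
  signal <- matrix(0, h, w)
  for (i in seq_len(nrow(truth))) {
    r <- truth$radius[i]
    x0 <- truth$x[i]; y0 <- truth$y[i]
    cols <- max(1, floor(x0 - r - 2)):min(w, ceiling(x0 + r + 2))
    rows <- max(1, floor(y0 - r - 2)):min(h, ceiling(y0 + r + 2))
    dx2 <- outer(rows - y0, cols - x0, function(a, b) a^2 + b^2)
    disk <- dx2 <= r^2
    amp <- values[i] - background
    sub <- signal[rows, cols, drop = FALSE]
    signal[rows, cols] <- pmax(sub, disk * amp)
  }
  if (edge_sigma > 0) signal <- EBImage::gblur(signal, sigma = edge_sigma)
  clean <- pmax(background + signal, 0)
  noisy <- rpois(length(clean), clean) +
    rnorm(length(clean), 0, read_sd)
  matrix(pmax(noisy, 0), h, w)
}

#' Simulate a multi-channel colony image with ground truth
#'
#' Renders nuclei as smooth-edged disks over a uniform background, with
#' Poisson shot noise plus Gaussian read noise, for a DAPI channel and the
#' marker channels declared in `expr`. Per-nucleus true intensities are drawn
#' from the ON/OFF log-normal mixture of [expression_params()], with the
#' response channel's state tied to the driver's fold over background through
#' the Hill link.
#'
#' @param colony A [colony_params()] object.
#' @param expr An [expression_params()] object.
#' @return A list with elements:
#'   * `image`: an [image_stack()] of noisy rendered channels;
#'   * `truth`: a tibble with one row per nucleus — `nucleus`, `colony`,
#'     `x`, `y` (center, pixels; x = column, origin top-left), `radius`,
#'     one column of true mean intensity per channel, `driver_positive`,
#'     `true_fold`, `p_response_on` and `response_on`.
#' @export
generate_colony_image <- function(colony, expr) {
  stopifnot(inherits(colony, "colony_params"), inherits(expr, "expression_params"))
  withr::with_seed(colony$seed, {
    pts <- place_nuclei(colony)
    n <- nrow(pts)
    radius <- pmax(2, rnorm(n, colony$nucleus_radius_px, colony$nucleus_radius_sd))
    states <- sample_expression(n, expr)
    truth <- tibble::tibble(
      nucleus = seq_len(n), colony = pts$colony,
      x = pts$x, y = pts$y, radius = radius
    )
    truth <- dplyr::bind_cols(truth, states[, c(expr$channels,
                                                "driver_positive", "true_fold",
                                                "p_response_on", "response_on")])
    channels <- lapply(expr$channels, function(ch) {
      render_channel(truth, truth[[ch]], colony$image_shape_px,
                     expr$background_level, expr$read_noise_sd)
    })
    names(channels) <- expr$channels
    list(image = image_stack(channels), truth = truth)
  })
}

#' Simulate an image-free single-cell intensity table
#'
#' Draws per-cell driver and response intensities from the ON/OFF log-normal
#' mixture of [expression_params()]. The driver is ON in
#' `fraction_driver_positive` of cells; the response state is Bernoulli with
#' probability given by the repressive Hill link evaluated at the cell's
#' realized driver fold over background.
#'
#' @param n_cells Number of cells (>= 1).
#' @param expr An [expression_params()] object (its `seed` is used).
#' @return A tibble with one row per cell: `cell`, one intensity column per
#'   channel, `driver_positive`, `true_fold`, `p_response_on`, `response_on`.
#' @export
generate_cell_table <- function(n_cells, expr) {
  stopifnot(inherits(expr, "expression_params"),
            is.numeric(n_cells), length(n_cells) == 1,
            is.finite(n_cells), n_cells >= 1)
  withr::with_seed(expr$seed, {
    states <- sample_expression(as.integer(n_cells), expr)
    dplyr::bind_cols(tibble::tibble(cell = seq_len(n_cells)), states)
  })
}
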