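#' Parameters for synthetic single-molecule FISH spots
#'
#' @param n_spots_per_cell Mean spot (transcript) count per cell; either a
#'   single mean shared by all cells or a vector with one mean per labeled
#'   cell (in increasing label order), e.g. to couple transcript abundance
#'   to a per-cell protein state.
#' @param count_model `"poisson"` draws per-cell counts from a Poisson with
#'   that mean; `"fixed"` gives every cell exactly `n_spots_per_cell` spots.
#' @param spot_sigma_px Lateral Gaussian sigma of a rendered spot (pixels).
#' @param sigma_z_factor Axial sigma as a multiple of `spot_sigma_px`
#'   (axial PSFs are elongated).
#' @param amplitude Peak spot intensity above baseline.
#' @param noise_sd Gaussian noise standard deviation; `amplitude / noise_sd`
#'   is the spot SNR and must be positive.
#' @param z_planes Number of z planes in the rendered stack.
#' @param min_separation_px Minimum distance between spots within one cell;
#'   diffraction-limited spots closer than this are unresolvable even in
#'   principle, so the generator only draws resolvable configurations.
#' @param seed Integer seed.
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(n_spots_per_cell = 15,
                        count_model = c("poisson", "fixed"),
                        spot_sigma_px = 1.5,
                        sigma_z_factor = 2,
                        amplitude = 100,
                        noise_sd = 10,
                        z_planes = 9,
                        min_separation_px = 5,
                        seed = 1L) {
  count_model <- match.arg(count_model)
  stopifnot(all(n_spots_per_cell >= 0), spot_sigma_px > 0, sigma_z_factor > 0,
            amplitude > 0, noise_sd > 0, z_planes >= 1,
            min_separation_px >= 0,
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  structure(list(n_spots_per_cell = n_spots_per_cell,
                 count_model = count_model,
                 spot_sigma_px = spot_sigma_px,
                 sigma_z_factor = sigma_z_factor,
                 amplitude = amplitude, noise_sd = noise_sd,
                 z_planes = as.integer(z_planes),
                 min_separation_px = min_separation_px,
                 seed = as.integer(seed)),
            class = "spot_params")
}

#' Simulate a 3-D smFISH spot stack with ground truth
#'
#' Places per-cell transcript spots uniformly inside each labeled cell mask
#' (respecting the resolvability separation in `spots`) and renders them as
#' 3-D Gaussians over Gaussian noise.
#'
#' @param labels Integer label matrix (0 = background) assigning pixels to
#'   cells; must contain at least one labeled cell.
#' @param spots A [spot_params()] object. A warning is issued when
#'   `spot_sigma_px` is at least as large as the typical cell radius, since
#'   spots may then merge.
#' @return A list: `stack` (array `[y, x, z]`) and `truth`, a tibble of true
#'   spot coordinates `x`, `y`, `z` and owning `cell` label.
#' @export
generate_spot_stack <- function(labels, spots) {
  stopifnot(inherits(spots, "spot_params"), is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) stop("at least one labeled cell is required",
                             call. = FALSE)
  mean_area <- mean(tabulate(labels[labels > 0])[ids])
  if (spots$spot_sigma_px >= sqrt(mean_area / pi)) {
    warning("spot sigma is as large as the typical cell radius; spots may merge")
  }
  means <- spots$n_spots_per_cell
  if (length(means) == 1) means <- rep(means, length(ids))
  if (length(means) != length(ids)) {
    stop("n_spots_per_cell must be a scalar or have one mean per labeled cell",
         call. = FALSE)
  }
  h <- nrow(labels); w <- ncol(labels); nz <- spots$z_planes
  withr::with_seed(spots$seed, {
    xs <- ys <- zs <- cs <- numeric(0)
    for (ki in seq_along(ids)) {
      k <- ids[ki]
      n_k <- switch(spots$count_model,
                    poisson = rpois(1, means[ki]),
                    fixed = round(means[ki]))
      if (n_k == 0) next
      pix <- which(labels == k)
      px <- (pix - 1) %/% h + 1
      py <- (pix - 1) %% h + 1
      kx <- ky <- numeric(0)
      for (i in seq_len(n_k)) {
        placed <- FALSE
        for (attempt in seq_len(2000)) {
          j <- sample.int(length(pix), 1)
          cx <- px[j] + runif(1, -0.5, 0.5)
          cy <- py[j] + runif(1, -0.5, 0.5)
          if (length(kx) == 0 ||
              min((kx - cx)^2 + (ky - cy)^2) >= spots$min_separation_px^2) {
            kx <- c(kx, cx); ky <- c(ky, cy); placed <- TRUE; break
          }
        }
        if (!placed) {
          stop("cell ", k, " is too small for ", n_k,
               " spots at the minimum separation", call. = FALSE)
        }
      }
      xs <- c(xs, kx); ys <- c(ys, ky)
      zs <- c(zs, runif(n_k, 1, nz)); cs <- c(cs, rep(k, n_k))
    }
    stack <- array(rnorm(h * w * nz, 0, spots$noise_sd), dim = c(h, w, nz))
    stack <- pmax(stack, 0)
    sxy <- spots$spot_sigma_px; sz <- sxy * spots$sigma_z_factor
    half <- ceiling(3 * sxy)
    for (i in seq_along(xs)) {
      rows <- max(1, floor(ys[i] - half)):min(h, ceiling(ys[i] + half))
      cols <- max(1, floor(xs[i] - half)):min(w, ceiling(xs[i] + half))
      planes <- max(1, floor(zs[i] - 3 * sz)):min(nz, ceiling(zs[i] + 3 * sz))
      gy <- exp(-(rows - ys[i])^2 / (2 * sxy^2))
      gx <- exp(-(cols - xs[i])^2 / (2 * sxy^2))
      gz <- exp(-(planes - zs[i])^2 / (2 * sz^2))
      blob <- spots$amplitude * outer(gy, gx)
      for (p in seq_along(planes)) {
        stack[rows, cols, planes[p]] <- stack[rows, cols, planes[p]] +
          blob * gz[p]
      }
    }
    list(stack = stack,
         truth = tibble::tibble(x = xs, y = ys, z = zs, cell = as.integer(cs)))
  })
}

#' Laplacian-of-Gaussian blob filter
#'
#' Convolves each plane with a scale-normalized, negated Laplacian-of-
#' Gaussian kernel, so diffraction-limited spots become local maxima. The
#' operator is linear; its response to a constant image is ~0.
#'
#' @param stack 2-D matrix or 3-D array `[y, x, z]` (each z plane is
#'   filtered independently).
#' @param sigma_px Kernel sigma in pixels; matched to the spot size. Must be
#'   below a quarter of the smallest lateral image dimension.
#' @return Filtered matrix/array of the same shape.
#' @export
log_filter <- function(stack, sigma_px) {
  stopifnot(is.numeric(sigma_px), length(sigma_px) == 1, sigma_px > 0)
  d <- dim(stack)
  if (sigma_px >= min(d[1:2]) / 4) {
    stop("sigma must be smaller than a quarter of the image size", call. = FALSE)
  }
  half <- ceiling(4 * sigma_px)
  ax <- -half:half
  g2 <- outer(ax^2, ax^2, "+")
  # scale-normalized LoG, negated so blobs become maxima; zero-mean kernel
  kern <- -(g2 / (2 * sigma_px^2) - 1) * exp(-g2 / (2 * sigma_px^2))
  kern <- kern - mean(kern)
  apply_plane <- function(m) EBImage::filter2(m, kern, boundary = "replicate")
  if (length(d) == 2 || is.null(d)) {
    apply_plane(stack)
  } else {
    out <- stack
    for (z in seq_len(d[3])) out[, , z] <- apply_plane(stack[, , z])
    out
  }
}

#' Maximum-intensity projection over z
#'
#' @param stack 3-D array `[y, x, z]`. A 2-D input is returned unchanged
#'   with a warning.
#' @return 2-D matrix of per-pixel maxima over z.
#' @export
max_intensity_projection <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2) {
    warning("input has no z dimension; returning it unchanged")
    return(stack)
  }
  stopifnot(length(d) == 3)
  out <- stack[, , 1]
  for (z in seq_len(d[3])[-1]) out <- pmax(out, stack[, , z])
  out
}

#' Detect spots in a LoG-filtered image
#'
#' Finds local maxima of the filtered maximum-intensity projection above a
#' threshold, with non-maximum suppression inside `min_separation_px`. The
#' default threshold is robust: `median + k * MAD` of the filtered image
#' (`k = 5`); an absolute threshold can be given instead.
#'
#' @param filtered Output of [log_filter()]; a 3-D input is projected with
#'   [max_intensity_projection()] first.
#' @param threshold Either `"k_sigma"` (robust, default) or `"absolute"`.
#' @param k Multiplier for the `"k_sigma"` rule.
#' @param value Absolute threshold for `threshold = "absolute"`.
#' @param min_separation_px Minimum distance between retained calls.
#' @return A `SpotCalls` tibble: `x`, `y` (pixel coordinates of the maxima),
#'   `intensity` (filtered response at the call).
#' @export
detect_spots <- function(filtered, threshold = c("k_sigma", "absolute"),
                         k = 5, value = NULL, min_separation_px = 3) {
  threshold <- match.arg(threshold)
  if (length(dim(filtered)) == 3) {
    filtered <- max_intensity_projection(filtered)
  }
  stopifnot(is.matrix(filtered), min_separation_px >= 1)
  thr <- if (threshold == "k_sigma") {
    median(filtered) + k * mad(filtered)
  } else {
    if (is.null(value) || !is.finite(value)) {
      stop("absolute threshold requires a finite value", call. = FALSE)
    }
    value
  }
  win <- 2L * as.integer(ceiling(min_separation_px)) + 1L
  mx <- EBImage::dilate(filtered, EBImage::makeBrush(win, "box"))
  cand <- which(filtered >= mx - 1e-12 & filtered > thr)
  if (length(cand) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          intensity = numeric(0)))
  }
  cy <- (cand - 1) %% nrow(filtered) + 1
  cx <- (cand - 1) %/% nrow(filtered) + 1
  iv <- filtered[cand]
  # greedy suppression by decreasing response, for plateau ties
  ord <- order(-iv)
  keep <- logical(length(ord))
  for (i in ord) {
    if (!any(keep) ||
        min((cx[keep] - cx[i])^2 + (cy[keep] - cy[i])^2) >= min_separation_px^2) {
      keep[i] <- TRUE
    }
  }
  tibble::tibble(x = cx[keep], y = cy[keep], intensity = iv[keep])
}

#' Assign detected spots to segmented cells
#'
#' Each spot inherits the label at its rounded (x, y) position; label 0
#' pixels put the spot in the unassigned bucket (`cell = 0`).
#'
#' @param spots A `SpotCalls` tibble from [detect_spots()].
#' @param labels Integer label matrix sharing the spots' coordinate frame.
#' @return A list: `spots` (input with a `cell` column) and `counts`, a
#'   tibble of per-cell spot counts covering every label in `labels` plus
#'   the unassigned bucket `cell = 0`.
#' @export
assign_spots_to_cells <- function(spots, labels) {
  stopifnot(is.matrix(labels), all(c("x", "y") %in% names(spots)))
  xi <- round(spots$x); yi <- round(spots$y)
  if (nrow(spots) > 0 &&
      (any(xi < 1 | xi > ncol(labels)) || any(yi < 1 | yi > nrow(labels)))) {
    stop("spot coordinates fall outside the label image", call. = FALSE)
  }
  cell <- if (nrow(spots) > 0) labels[cbind(yi, xi)] else integer(0)
  ids <- sort(unique(c(0L, labels[labels > 0])))
  counts <- vapply(ids, function(k) sum(cell == k), integer(1))
  list(spots = dplyr::mutate(spots, cell = as.integer(cell)),
       counts = tibble::tibble(cell = as.integer(ids), n_spots = counts))
}
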