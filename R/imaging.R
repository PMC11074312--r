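#' Subtract image background
#'
#' Two estimators are provided. `"percentile"` takes a global percentile of
#' the pixel intensities as a scalar background; with mostly-background
#' images a low percentile (default 25) lands on the background plateau.
#' The percentile is read from a lightly smoothed copy of the image
#' (Gaussian, 2 px), so shot noise does not bias the percentile below the
#' plateau level; the correction itself is applied to the original image.
#' `"rolling_ball"` estimates a spatially varying background as the
#' grayscale morphological opening of the image with a disc structuring
#' element of the given radius (the classic rolling-ball approximation).
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param method `"percentile"` or `"rolling_ball"`.
#' @param p Percentile in (0, 100) for the percentile method.
#' @param radius_px Ball radius in pixels for the rolling-ball method; must
#'   be smaller than half the smallest image dimension.
#' @return A list with `image` (corrected, clipped at zero) and `background`
#'   (a scalar for `"percentile"`, a matrix for `"rolling_ball"`).
#' @export
subtract_background <- function(image,
                                method = c("percentile", "rolling_ball"),
                                p = 25, radius_px = 50) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (method == "percentile") {
    if (!is.finite(p) || p <= 0 || p >= 100) {
      stop("percentile p must lie in (0, 100)", call. = FALSE)
    }
    smoothed <- if (min(dim(image)) >= 16) EBImage::gblur(image, 2) else image
    bg <- unname(quantile(smoothed, p / 100))
    # snap to the nearest observed pixel value so flat plateaus are exact
    bg <- image[which.min(abs(image - bg))]
    list(image = pmax(image - bg, 0), background = bg)
  } else {
    if (!is.finite(radius_px) || radius_px < 1 ||
        2 * radius_px + 1 > min(dim(image))) {
      stop("rolling-ball radius must be >= 1 px and smaller than half the image",
           call. = FALSE)
    }
    brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, shape = "disc")
    scale <- max(image, 1)
    bg <- EBImage::opening(image / scale, brush) * scale
    list(image = pmax(image - bg, 0), background = bg)
  }
}

#' Segment nuclei in a DAPI channel
#'
#' Classical marker-controlled watershed pipeline: Gaussian smoothing,
#' global threshold (Otsu or manual), hole filling, then distance-transform
#' peaks (separated by at least `min_distance_px`) as markers from which the
#' foreground is partitioned by watershed-style propagation on the inverted
#' distance map, splitting touching nuclei. An area filter removes debris
#' and merged blobs. Fully deterministic.
#' Segmentation is pluggable: externally produced label masks (e.g. from a
#' trained model) can be loaded with [read_labels()] and fed directly to
#' [measure_nuclei()].
#'
#' @param dapi 2-D numeric matrix (nuclear stain).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param threshold `"otsu"` or `"manual"`.
#' @param manual_value Threshold on the original intensity scale when
#'   `threshold = "manual"`.
#' @param min_distance_px Minimum separation between watershed seed maxima;
#'   controls how aggressively touching nuclei are split.
#' @param seed_min_radius_px Distance-map height a peak must reach to seed a
#'   nucleus; suppresses spurious seeds in thin mask bridges.
#' @param area_bounds Numeric `c(min, max)` area in px^2, or `NULL` for the
#'   default `[0.3, 3]` times the median detected area.
#' @return An integer label matrix (0 = background, contiguous labels from 1).
#' @export
segment_nuclei <- function(dapi, smooth_sigma = 1,
                           threshold = c("otsu", "manual"),
                           manual_value = NULL,
                           min_distance_px = 6,
                           seed_min_radius_px = 2.5,
                           area_bounds = NULL) {
  threshold <- match.arg(threshold)
  stopifnot(is.matrix(dapi), all(is.finite(dapi)), smooth_sigma >= 0,
            min_distance_px >= 1)
  top <- max(dapi)
  if (top <= 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  norm <- dapi / top
  sm <- if (smooth_sigma > 0) EBImage::gblur(norm, sigma = smooth_sigma) else norm
  thr <- if (threshold == "otsu") {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    if (is.null(manual_value) || !is.finite(manual_value)) {
      stop("manual threshold requires a finite manual_value", call. = FALSE)
    }
    manual_value / top
  }
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  dms <- EBImage::gblur(dm, 1)
  win <- 2L * as.integer(min_distance_px) + 1L
  mx <- EBImage::dilate(dms, EBImage::makeBrush(win, "box"))
  seeds <- EBImage::bwlabel((dms >= mx - 1e-9) & (dm > seed_min_radius_px))
  if (max(seeds) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  labels <- EBImage::propagate(-dm, seeds, mask = mask)
  labels <- matrix(as.integer(labels), nrow(dapi), ncol(dapi))
  areas <- tabulate(labels[labels > 0])
  if (is.null(area_bounds)) {
    med <- median(areas[areas > 0])
    area_bounds <- c(0.3, 3) * med
  }
  keep <- which(areas >= area_bounds[1] & areas <= area_bounds[2])
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  pos <- labels > 0
  out[pos] <- relabel[labels[pos]]
  out
}

#' Measure per-nucleus intensities and centroids
#'
#' For every label, computes the unweighted mean of each channel over the
#' label's pixels, the pixel area, and the centroid as the plain mean of the
#' member pixel coordinates (x = column, y = row, origin top-left, pixel
#' centers at integers).
#'
#' @param labels Integer label matrix from [segment_nuclei()] or
#'   [read_labels()].
#' @param stack An [image_stack()] whose channels share the labels' shape,
#'   or a named list of matrices.
#' @return A `CellTable` tibble: `label`, `x`, `y`, `area`, then one mean
#'   intensity column per channel.
#' @export
measure_nuclei <- function(labels, stack) {
  if (inherits(stack, "image_stack")) stack <- stack$channels
  stopifnot(is.list(stack), length(stack) >= 1, !is.null(names(stack)))
  for (ch in names(stack)) {
    if (!identical(dim(stack[[ch]])[1:2], dim(labels)[1:2])) {
      stop("channel '", ch, "' does not share the label image's shape",
           call. = FALSE)
    }
  }
  ids <- labels[labels > 0]
  if (length(ids) == 0) {
    out <- tibble::tibble(label = integer(0), x = numeric(0), y = numeric(0),
                          area = numeric(0))
    for (ch in names(stack)) out[[ch]] <- numeric(0)
    return(out)
  }
  n_lab <- max(ids)
  area <- tabulate(ids, nbins = n_lab)
  present <- which(area > 0)
  pos <- which(labels > 0)
  rows <- (pos - 1) %% nrow(labels) + 1
  cols <- (pos - 1) %/% nrow(labels) + 1
  sum_by <- function(v) {
    s <- numeric(n_lab)
    t <- rowsum(v, ids)
    s[as.integer(rownames(t))] <- t[, 1]
    s
  }
  out <- tibble::tibble(
    label = present,
    x = sum_by(cols)[present] / area[present],
    y = sum_by(rows)[present] / area[present],
    area = as.numeric(area[present])
  )
  for (ch in names(stack)) {
    v <- stack[[ch]]
    out[[ch]] <- sum_by(as.numeric(v[pos]))[present] / area[present]
  }
  out
}
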