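#' Nearest-neighbor distances of a point set
#'
#' For each point (nuclear centroid), the Euclidean distance to its closest
#' other point. Distances are exact: pairwise distances are computed in
#' blocks so memory stays bounded for large point sets.
#'
#' @param x,y Numeric coordinate vectors of equal length (>= 2), in pixels
#'   (or physical units if centroids were scaled beforehand).
#' @return Numeric vector of per-point nearest-neighbor distances.
#' @export
nearest_neighbor_distances <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 2) stop("nearest-neighbor distance needs at least 2 points",
                  call. = FALSE)
  block <- 512L
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Compare two nearest-neighbor distance distributions
#'
#' Two-sample Kolmogorov-Smirnov test plus medians, used to contrast colony
#' packing between conditions (e.g. tightly packed vs spread colonies).
#'
#' @param a,b Non-empty numeric distance vectors.
#' @return A list: `ks_statistic`, `p_value`, `median_a`, `median_b`,
#'   `median_difference` (`median_b - median_a`), `n_a`, `n_b`.
#' @export
compare_nn_distributions <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  ks <- suppressWarnings(ks.test(a, b))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       median_a = median(a), median_b = median(b),
       median_difference = median(b) - median(a),
       n_a = length(a), n_b = length(b))
}
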