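#' Fold-over-background normalization
#'
#' Normalizes per-cell nuclear intensities to the image background estimate:
#' `fold = intensity / background`. Background-level cells therefore sit at
#' fold ~ 1, and the conventional 2x and 4x fold thresholds are expressed in
#' these units.
#'
#' @param intensity Numeric vector of per-cell mean nuclear intensities.
#' @param background Positive scalar background estimate (typically the
#'   `background` element returned by [subtract_background()]).
#' @return Numeric vector of folds, clipped below at machine epsilon.
#' @export
fold_over_background <- function(intensity, background) {
  if (!is.numeric(background) || length(background) != 1 ||
      !is.finite(background) || background <= 0) {
    stop("background must be a positive finite scalar", call. = FALSE)
  }
  stopifnot(is.numeric(intensity), all(is.finite(intensity)))
  pmax(intensity / background, .Machine$double.eps)
}

#' Default fold bins for dose-response analysis
#'
#' Bin edges on the fold-over-background axis. The defaults
#' `[0, 1.5), [1.5, 2), [2, 4), [4, Inf)` carry labels
#' `negative`, `low`, `2-4x`, `>=4x`; background-level cells (fold ~ 1)
#' land in the first bin.
#'
#' @param edges Strictly increasing numeric vector of bin edges starting at
#'   0 and ending at `Inf`.
#' @param labels Character labels, one per bin.
#' @return An object of class `fold_bins`.
#' @export
fold_bins <- function(edges = c(0, 1.5, 2, 4, Inf),
                      labels = c("negative", "low", "2-4x", ">=4x")) {
  stopifnot(is.numeric(edges), length(edges) >= 2, all(diff(edges) > 0),
            edges[1] <= 1, length(labels) == length(edges) - 1)
  structure(list(edges = edges, labels = labels), class = "fold_bins")
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Classify cells as ON or OFF
#'
#' Two methods. `"gmm2_log"` fits a two-component Gaussian mixture to the
#' log intensities (deterministic model-based initialization) and assigns
#' each cell to the component with posterior probability >= 0.5; the ON
#' state is the component with the larger mean. `"threshold"` declares a
#' cell ON when its value is at or above `cutoff` (inclusive). Both return
#' the mixture separation statistic
#' \deqn{D = |\mu_1 - \mu_2| / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}}
#' on the log scale (`NA` for the threshold method or degenerate fits).
#'
#' @param values Positive per-cell values (intensities or folds).
#' @param method `"gmm2_log"` or `"threshold"`.
#' @param cutoff Threshold for the `"threshold"` method (ON if `value >=
#'   cutoff`).
#' @return A list with `state` (logical, `TRUE` = ON), `method`, `D`, and for
#'   the mixture fit `means`, `sds`, `proportions` on the log scale, plus
#'   `degenerate` (`TRUE` when all values are equal and a single-population
#'   verdict is returned).
#' @export
classify_on_off <- function(values, method = c("gmm2_log", "threshold"),
                            cutoff = 2) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (method == "threshold") {
    return(list(state = values >= cutoff, method = method, D = NA_real_,
                degenerate = FALSE))
  }
  if (length(values) < 20) {
    stop("gmm2_log needs at least 20 cells", call. = FALSE)
  }
  if (any(values <= 0)) stop("gmm2_log needs positive values", call. = FALSE)
  lv <- log(values)
  if (diff(range(lv)) < .Machine$double.eps^0.5) {
    return(list(state = rep(TRUE, length(values)), method = method,
                D = NA_real_, degenerate = TRUE))
  }
  fit <- mclust::Mclust(lv, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    fit <- mclust::Mclust(lv, G = 2, modelNames = "E", verbose = FALSE)
  }
  if (is.null(fit)) {
    return(list(state = rep(TRUE, length(values)), method = method,
                D = NA_real_, degenerate = TRUE))
  }
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  on_comp <- which.max(mu)
  post_on <- fit$z[, on_comp]
  D <- abs(diff(mu)) / sqrt(mean(sig^2))
  list(state = post_on >= 0.5, method = method, D = unname(D),
       means = unname(mu), sds = unname(sig),
       proportions = unname(fit$parameters$pro), degenerate = FALSE)
}

#' Dose-response of the response-negative fraction over driver fold bins
#'
#' Bins cells by the driver channel's fold over background and reports, per
#' bin, the number of cells and the fraction in which the response channel is
#' OFF, with a Wilson 95% confidence interval. With a repressive driver the
#' fraction rises with fold — the dose-response signature of the switch.
#'
#' @param fold Per-cell driver fold over background.
#' @param response_on Logical per-cell response state (`TRUE` = ON).
#' @param bins A [fold_bins()] object.
#' @return A `DoseResponseCurve` tibble: `bin`, `n_cells`,
#'   `fraction_negative` (`NA` for empty bins), `ci_lo`, `ci_hi`.
#' @export
dose_response <- function(fold, response_on, bins = fold_bins()) {
  stopifnot(inherits(bins, "fold_bins"), length(fold) == length(response_on),
            is.logical(response_on))
  idx <- cut(fold, breaks = bins$edges, labels = bins$labels,
             right = FALSE, include.lowest = TRUE)
  out <- lapply(seq_along(bins$labels), function(b) {
    in_bin <- which(as.integer(idx) == b)
    n <- length(in_bin)
    k <- sum(!response_on[in_bin])
    ci <- wilson_ci(k, n)
    tibble::tibble(bin = bins$labels[b], n_cells = n,
                   fraction_negative = if (n > 0) k / n else NA_real_,
                   ci_lo = ci[1], ci_hi = ci[2])
  })
  dplyr::bind_rows(out)
}

#' Correlation between two channels
#'
#' Pearson correlation and least-squares line between two per-cell intensity
#' channels, optionally on the log10 scale (the default, as nuclear
#' intensities commonly span orders of magnitude).
#'
#' @param a,b Numeric per-cell intensity vectors of equal length (>= 3);
#'   strictly positive when `log = TRUE`.
#' @param log Correlate `log10` values?
#' @return A list: `r`, `slope`, `intercept`, `n`, `log`. With zero variance
#'   in either channel, `r` is `NA` and `degenerate` is `TRUE`.
#' @export
correlate_channels <- function(a, b, log = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 3, all(is.finite(a)), all(is.finite(b)))
  if (log) {
    if (any(a <= 0) || any(b <= 0)) {
      stop("log-scale correlation needs strictly positive values", call. = FALSE)
    }
    a <- log10(a); b <- log10(b)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = length(a), log = log, degenerate = TRUE))
  }
  fit <- lm(b ~ a)
  list(r = unname(cor(a, b)), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = length(a), log = log,
       degenerate = FALSE)
}

#' Fraction of cells positive for a channel
#'
#' Classifies cells with [classify_on_off()] and reports the ON proportion
#' with a Wilson 95% confidence interval.
#'
#' @inheritParams classify_on_off
#' @return A list: `fraction`, `n`, `ci_lo`, `ci_hi`, plus the classifier
#'   output as `classification`.
#' @export
fraction_positive <- function(values, method = c("gmm2_log", "threshold"),
                              cutoff = 2) {
  if (length(values) == 0) stop("empty cell table", call. = FALSE)
  cls <- classify_on_off(values, method, cutoff)
  k <- sum(cls$state); n <- length(values)
  ci <- wilson_ci(k, n)
  list(fraction = k / n, n = n, ci_lo = ci[1], ci_hi = ci[2],
       classification = cls)
}

#' Equal-count Low/Med/High gating
#'
#' Ranks cells by a channel value and splits them into three contiguous rank
#' groups of equal size (sizes differ by at most one cell; any remainder
#' goes to Low first, then Med). Ties are broken by stable input order, so
#' identical values still yield balanced gates.
#'
#' @param values Numeric per-cell channel values (length >= 3).
#' @return A factor of length `length(values)` with levels
#'   `Low`, `Med`, `High`, aligned with the input order.
#' @export
gate_equal_thirds <- function(values) {
  n <- length(values)
  stopifnot(is.numeric(values), n >= 3, all(is.finite(values)))
  ord <- order(values)                   # stable for ties (radix on doubles)
  base <- n %/% 3; rem <- n %% 3
  sizes <- base + c(rem >= 1, rem >= 2, 0)
  gate_ranked <- rep(c("Low", "Med", "High"), times = sizes)
  out <- character(n)
  out[ord] <- gate_ranked
  factor(out, levels = c("Low", "Med", "High"))
}
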