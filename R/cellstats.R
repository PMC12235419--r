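#' Geometric mean of single-cell intensities
#'
#' `exp(mean(log(x)))` — the appropriate central tendency for
#' log-normally distributed cellular bioluminescence intensities.
#'
#' @param x Positive intensities (photons per minute).
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(10, 1000))  # 100
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("empty intensity set", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be positive and finite (background-subtracted ",
         "values <= 0 are rejected, not dropped)", call. = FALSE)
  exp(mean(log(x)))
}

#' Kolmogorov-Smirnov test of log-normality
#'
#' Tests whether intensities are log-normal by a one-sample KS test of the
#' log-transformed values against a normal law. With `method = "ks"`
#' (default) the normal parameters are the sample mean and SD of the logs
#' and the plain asymptotic KS p-value is reported; estimating the
#' parameters from the same sample makes that p-value conservative. The
#' `"lilliefors"` method applies the Lilliefors correction (via
#' \pkg{nortest}), giving a test calibrated at its nominal level.
#'
#' @param x Positive intensities, at least 5 values.
#' @param method `"ks"` (plain, parameters estimated) or `"lilliefors"`.
#' @return A list with `statistic`, `p_value`, `n` and `method`.
#' @export
lognormality_ks <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  if (length(x) < 5L) stop("need at least 5 values", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be positive and finite", call. = FALSE)
  lx <- log(x)
  if (stats::sd(lx) == 0)
    stop("degenerate input: zero variance on the log scale", call. = FALSE)
  if (method == "ks") {
    ht <- suppressWarnings(
      stats::ks.test(lx, "pnorm", mean = mean(lx), sd = stats::sd(lx)))
  } else {
    ht <- nortest::lillie.test(lx)
  }
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       n = length(x), method = method)
}

#' Fold difference of two intensity sets
#'
#' Ratio of geometric means, `geometric_mean(a) / geometric_mean(b)`.
#'
#' @param a,b Positive intensity vectors.
#' @return The fold difference (dimensionless).
#' @export
fold_difference <- function(a, b) {
  geometric_mean(a) / geometric_mean(b)
}

#' Histogram of intensities on a log10 axis
#'
#' Equal-width bins in log10 space spanning the data, as used for
#' single-cell intensity distributions (log-normal data look symmetric on
#' this axis, with the modal bin near the geometric mean).
#'
#' @param x Positive intensities.
#' @param n_bins Number of bins (>= 2).
#' @return A list with `breaks_log10`, `breaks` (back-transformed),
#'   `counts` and `mids_log10`. Counts sum to `length(x)`.
#' @export
histogram_log <- function(x, n_bins = 20L) {
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be positive and finite", call. = FALSE)
  lx <- log10(x)
  rng <- range(lx)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks_log10 = breaks, breaks = 10^breaks, counts = h$counts,
       mids_log10 = h$mids)
}
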