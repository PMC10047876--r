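#' Fisher-transformation pooling of agreement coefficients
#'
#' Averages bounded coefficients on the unbounded `atanh` scale:
#' `z_j = atanh(c_j)`, pooled value `tanh(mean(z))`. The confidence
#' interval is formed from the standard error of the mean in transform
#' space, `sd(z)/sqrt(m)`, and back-transformed; it is therefore a CI
#' for the mean coefficient, not a prediction interval for a new rater.
#'
#' @param coefficients Numeric vector of coefficients, each strictly
#'   inside (-1, 1).
#' @param conf Confidence level (default 0.95).
#'
#' @return A `pooled_result`: list with `estimate`, `z` (the
#'   transforms), `se_z` (se of the mean transform; `NA` for a single
#'   input), `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' fisher_pool(c(0.79, 0.83))$estimate  # 0.81 to 2 decimals
fisher_pool <- function(coefficients, conf = 0.95) {
  x <- as.numeric(coefficients)
  if (length(x) < 1L) stop("no coefficients to pool", call. = FALSE)
  if (anyNA(x)) stop("coefficients must not be missing", call. = FALSE)
  if (any(abs(x) >= 1)) {
    stop("coefficients of exactly +/-1 have an infinite Fisher ",
         "transform and cannot be pooled", call. = FALSE)
  }
  z <- atanh(x)
  m <- length(z)
  se_z <- if (m > 1L) stats::sd(z) / sqrt(m) else NA_real_
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  structure(
    list(estimate = tanh(mean(z)), z = z, se_z = se_z,
         ci_low = if (is.na(se_z)) NA_real_ else tanh(mean(z) - zc * se_z),
         ci_high = if (is.na(se_z)) NA_real_ else tanh(mean(z) + zc * se_z),
         n = m, conf = conf),
    class = "pooled_result"
  )
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Fisher-pooled coefficient: %.3f (n = %d", x$estimate, x$n))
  if (!is.na(x$se_z)) {
    cat(sprintf(", %.0f%% CI %.3f-%.3f", 100 * x$conf,
                x$ci_low, x$ci_high))
  }
  cat(")\n")
  invisible(x)
}

#' Benchmark scale for interpreting agreement coefficients
#'
#' Defines the interpretation bands (Landis-Koch style by default), the
#' critical value to subtract before banding, and the clinical-adequacy
#' threshold. The critical value is the sample-size-dependent constant
#' of Gwet's benchmarking method: only the part of the coefficient that
#' confidently exceeds chance is interpreted. For a study with 44
#' subjects, 10 raters and 4 categories the tabulated value is 0.08.
#'
#' @param bands Data.frame with columns `lower` (band lower bound,
#'   inclusive) and `label`, ordered by `lower`.
#' @param critical_value Non-negative constant subtracted from the
#'   estimate before band lookup (default 0.08).
#' @param adequacy_threshold Coefficient at or above which reliability
#'   is considered adequate for clinical use (default 0.61).
#'
#' @return A `benchmark_scale` list.
#' @export
benchmark_scale <- function(bands = NULL, critical_value = 0.08,
                            adequacy_threshold = 0.61) {
  if (is.null(bands)) {
    bands <- data.frame(
      lower = c(-1, 0, 0.21, 0.41, 0.61, 0.81),
      label = c("poor", "slight", "fair", "moderate", "substantial",
                "almost perfect"),
      stringsAsFactors = FALSE
    )
  }
  if (is.unsorted(bands$lower, strictly = TRUE)) {
    stop("band lower bounds must be strictly increasing", call. = FALSE)
  }
  if (critical_value < 0) stop("critical_value must be >= 0", call. = FALSE)
  if (adequacy_threshold <= 0 || adequacy_threshold >= 1) {
    stop("adequacy_threshold must be in (0, 1)", call. = FALSE)
  }
  structure(list(bands = bands, critical_value = critical_value,
                 adequacy_threshold = adequacy_threshold),
            class = "benchmark_scale")
}

#' Benchmark an agreement coefficient
#'
#' Subtracts the scale's critical value from the estimate, looks up the
#' interpretation band containing the resulting "significant part", and
#' flags clinical adequacy of the (unsubtracted) estimate.
#'
#' @param estimate Agreement coefficient in (-1, 1].
#' @param scale A [benchmark_scale()].
#'
#' @return List with `significant_part`, `band`, `adequate`.
#' @export
#' @examples
#' benchmark_coefficient(0.69)  # significant part 0.61, "substantial"
benchmark_coefficient <- function(estimate, scale = benchmark_scale()) {
  if (estimate <= -1 || estimate > 1) {
    stop("estimate must lie in (-1, 1]", call. = FALSE)
  }
  sig <- estimate - scale$critical_value
  idx <- findInterval(sig, scale$bands$lower)
  band <- if (idx < 1L) scale$bands$label[1L] else scale$bands$label[idx]
  list(significant_part = sig, band = band,
       adequate = estimate >= scale$adequacy_threshold)
}

#' Precision criteria for percent agreement
#'
#' Study-design precision checks on a percent-agreement result: the
#' coefficient of variation (standard error over percent agreement)
#' must not exceed `cv_limit`, and the relative error (CI half-width
#' over percent agreement) must not exceed `rel_limit`. The full-width
#' relative error is also reported for transparency, since "width of
#' the confidence interval" is read by some authors as the full width;
#' the half-width is the flagged metric.
#'
#' @param result An `agreement_result` from [percent_agreement()] (or
#'   any result whose `estimate` is the percent agreement), or a plain
#'   list with `estimate`, `se`, `ci_low`, `ci_high`.
#' @param cv_limit Maximum tolerated coefficient of variation (default
#'   0.15).
#' @param rel_limit Maximum tolerated relative error (default 0.20).
#'
#' @return List with `cv`, `relative_error`, `relative_error_full`,
#'   `cv_ok`, `rel_ok` (limits are inclusive).
#' @export
precision_metrics <- function(result, cv_limit = 0.15, rel_limit = 0.20) {
  pa <- result$estimate
  if (is.null(pa) || is.na(pa) || pa <= 0) {
    stop("percent agreement must be positive", call. = FALSE)
  }
  cv <- result$se / pa
  half <- (result$ci_high - result$ci_low) / 2
  rel <- half / pa
  list(cv = cv, relative_error = rel, relative_error_full = 2 * rel,
       cv_ok = !is.na(cv) && cv <= cv_limit,
       rel_ok = !is.na(rel) && rel <= rel_limit)
}
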