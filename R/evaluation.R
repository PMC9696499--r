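# Model-qualification statistics: observed/predicted fold ratios, average
# fold error (geometric mean of ratios), two-fold flags, percentile bands for
# visual predictive checks, and box-whisker severity summaries.

#' Observed/predicted fold ratio
#'
#' @param observed,predicted Positive values (vectorized).
#' @return `observed / predicted`.
#' @export
fold_ratio <- function(observed, predicted) {
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop_field("observed", "must be positive")
  }
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop_field("predicted", "must be positive")
  }
  observed / predicted
}

#' Average fold error
#'
#' Geometric mean of observed/predicted ratios:
#' `AFE = 10^(mean(log10(ratio)))`.
#'
#' @param ratios Positive fold ratios.
#' @return The AFE (dimensionless).
#' @export
afe <- function(ratios) {
  if (!length(ratios)) stop_field("ratios", "must be non-empty")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop_field("ratios", "must be positive")
  }
  10^mean(log10(ratios))
}

#' Two-fold acceptance flags
#'
#' @param ratios Positive fold ratios.
#' @return Logical vector: `TRUE` iff the ratio lies in `[0.5, 2]` (inclusive
#'   at both boundaries).
#' @export
two_fold_flags <- function(ratios) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop_field("ratios", "must be positive")
  }
  ratios >= 0.5 & ratios <= 2
}

#' Per-timepoint percentile bands over a set of profiles
#'
#' Computes, at every common timepoint, the arithmetic mean, minimum, maximum
#' and the 5th/95th percentiles (linear interpolation between order
#' statistics, R quantile type 7).
#'
#' @param profiles A list (>= 2) of `pbpk_profile` objects on identical time
#'   grids, or a numeric matrix with one row per profile plus a `time` vector.
#' @param time Time grid when `profiles` is a matrix.
#' @return An object of class `pbpk_bands`: a data.frame with columns `time`,
#'   `mean`, `minimum`, `maximum`, `p5`, `p95`.
#' @export
percentile_bands <- function(profiles, time = NULL) {
  if (is.list(profiles)) {
    if (length(profiles) < 2L) stop_field("profiles", "need at least 2 profiles")
    stopifnot(all(vapply(profiles, inherits, logical(1), "pbpk_profile")))
    time <- profiles[[1L]]$time
    for (p in profiles) {
      if (length(p$time) != length(time) || any(p$time != time)) {
        stop("profiles are not on a common time grid", call. = FALSE)
      }
    }
    mat <- do.call(rbind, lapply(profiles, function(p) p$concentration))
  } else {
    mat <- as.matrix(profiles)
    if (is.null(time) || length(time) != ncol(mat)) {
      stop_field("time", "must match the matrix columns")
    }
    if (nrow(mat) < 2L) stop_field("profiles", "need at least 2 profiles")
  }
  q <- apply(mat, 2, stats::quantile, probs = c(0.05, 0.95), type = 7, names = FALSE)
  out <- data.frame(
    time = time,
    mean = colMeans(mat),
    minimum = apply(mat, 2, min),
    maximum = apply(mat, 2, max),
    p5 = q[1, ],
    p95 = q[2, ]
  )
  class(out) <- c("pbpk_bands", "data.frame")
  out
}

#' Box-whisker summary of an exposure metric
#'
#' Median with a seeded bootstrap percentile confidence interval for the
#' median (default 10,000 resamples, 95% level).
#'
#' @param values Numeric vector (>= 3 values), e.g. per-subject AUCs.
#' @param n_boot Bootstrap resamples.
#' @param conf_level Confidence level.
#' @param seed Seed for the bootstrap (restores the caller's RNG state).
#' @return A list with `median`, `ci_low`, `ci_high`, `conf_level`, `n`.
#' @export
box_summary <- function(values, n_boot = 10000L, conf_level = 0.95, seed = 1L) {
  if (length(values) < 3L) stop_field("values", "need at least 3 values")
  if (any(!is.finite(values))) stop_field("values", "must be finite")
  check_number(conf_level, "conf_level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  med <- stats::median(values)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::median(sample(values, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(median = med, ci_low = ci[1], ci_high = ci[2],
       conf_level = conf_level, n = length(values))
}
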