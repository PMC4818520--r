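#' Per-marker threshold from a null min-p distribution
#'
#' The per-marker threshold u at family-wise level alpha is the pointwise
#' p-value whose exceedance probability by the minimum p across all markers
#' is alpha; on the Monte-Carlo realization it is the empirical
#' alpha-quantile of the per-replicate minimum p-values (order statistic
#' `ceiling(alpha * s)`, lower tie value — conservative).  The Monte-Carlo
#' standard error maps the binomial error of the tail probability through a
#' local density estimate of the min-p distribution.
#'
#' @param d a `null_minp` distribution (any provenance).
#' @param alpha family-wise significance level in (0, 1); requires
#'   `n_samples * alpha >= 10`.
#' @return Object of class `threshold_result`: `alpha`,
#'   `per_marker_threshold`, `mc_se`, `n_samples`, `m`, `method`.
#' @export
per_marker_threshold <- function(d, alpha = 0.05) {
  mt_assert(inherits(d, "null_minp"), "not a null_minp distribution")
  mt_assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  s <- d$n_samples
  mt_assert(s * alpha >= 10,
            sprintf("insufficient samples: n_samples * alpha = %.1f < 10",
                    s * alpha))
  sp <- d$sorted
  k <- ceiling(alpha * s)
  u <- sp[k]
  # quantile SE: sqrt(a(1-a)/s) / f(u), f estimated from nearby order stats
  h <- max(1L, as.integer(round(0.005 * s)))
  lo <- sp[max(1L, k - h)]
  hi <- sp[min(s, k + h)]
  if (hi <= lo) {
    warning("degenerate min-p distribution near the requested quantile")
    mc_se <- 0
  } else {
    dens <- (min(s, k + h) - max(1L, k - h)) / s / (hi - lo)
    mc_se <- sqrt(alpha * (1 - alpha) / s) / dens
  }
  structure(list(alpha = alpha, per_marker_threshold = u, mc_se = mc_se,
                 n_samples = s, m = d$m, method = d$provenance),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result (%s): alpha = %g -> per-marker u = %.4g (mc_se %.2g; s = %d, m = %d)\n",
              x$method, x$alpha, x$per_marker_threshold, x$mc_se,
              x$n_samples, x$m))
  invisible(x)
}

#' Family-wise error rate at a pointwise threshold
#'
#' Fraction of replicate minimum p-values at or below u, with an exact
#' binomial 95 percent confidence interval.
#'
#' @param d a `null_minp` distribution.
#' @param u pointwise p-value threshold in (0, 1].
#' @return List with `p_alpha`, `ci` (length 2), `n_samples`.
#' @export
family_wise_error <- function(d, u) {
  mt_assert(inherits(d, "null_minp"), "not a null_minp distribution")
  mt_assert(is.numeric(u) && length(u) == 1 && u > 0 && u <= 1,
            "u must be a single value in (0, 1]")
  hits <- sum(d$min_p <= u)
  bt <- stats::binom.test(hits, d$n_samples)
  list(p_alpha = hits / d$n_samples, ci = as.numeric(bt$conf.int),
       n_samples = d$n_samples)
}

#' Bonferroni per-marker threshold
#'
#' @param alpha family-wise level.
#' @param m number of markers (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  mt_assert(is.numeric(m) && length(m) == 1 && m >= 1, "m must be >= 1")
  mt_assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  alpha / m
}

#' Sidak per-marker threshold (independence reference)
#'
#' @param alpha family-wise level.
#' @param m number of markers (>= 1).
#' @return `1 - (1 - alpha)^(1/m)`.
#' @export
sidak <- function(alpha, m) {
  mt_assert(is.numeric(m) && length(m) == 1 && m >= 1, "m must be >= 1")
  mt_assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  -expm1(log1p(-alpha) / m)
}

#' Threshold curve over a grid of significance levels
#'
#' Convenience wrapper evaluating [per_marker_threshold()] over a grid of
#' alpha values (default 0.001 to 0.10), for threshold-vs-level reports.
#'
#' @param d a `null_minp` distribution.
#' @param alphas numeric vector of levels.
#' @return Data frame with `alpha`, `threshold`, `mc_se`, plus `bonferroni`
#'   and `sidak` reference columns.
#' @export
threshold_curve <- function(d, alphas = c(0.001, 0.005, 0.01, 0.05, 0.10)) {
  rows <- lapply(alphas, function(a) {
    tr <- per_marker_threshold(d, a)
    data.frame(alpha = a, threshold = tr$per_marker_threshold,
               mc_se = tr$mc_se, bonferroni = bonferroni(a, d$m),
               sidak = sidak(a, d$m))
  })
  do.call(rbind, rows)
}
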