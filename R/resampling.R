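new_resampling_run <- function(min_p, m, provenance, pooled_p = NULL,
                               n_reps = length(min_p)) {
  d <- new_null_minp(min_p, m, provenance, n_reps)
  structure(list(min_p_dist = d, pooled_p = pooled_p, n_reps = n_reps,
                 provenance = provenance),
            class = "resampling_run")
}

#' @export
print.resampling_run <- function(x, ...) {
  cat(sprintf("resampling_run (%s): %d replicates over %d markers\n",
              x$provenance, x$n_reps, x$min_p_dist$m))
  invisible(x)
}

#' Parametric bootstrap of null phenotypes (gold standard)
#'
#' Samples null phenotype vectors `y* ~ N(0, V)` under the fitted mixed
#' model and recomputes the full association scan for each, recording the
#' per-replicate minimum p-value.  Mode `"fixedV"` reuses the fitted
#' covariance for every replicate and exploits `V^{-1/2} y* = z` (a
#' standard-normal vector), so replicate statistics are correlations of the
#' transformed genotypes with fresh white noise — the fast path.  Mode
#' `"full"` refits the variance components on every simulated phenotype and
#' runs the scan under the refitted model, the literal (slow) resampling
#' procedure; it refuses runs whose `n_reps * n^3` cost exceeds
#' `cost_budget`.
#'
#' @param g standardized [genotype_matrix()].
#' @param k [kinship_matrix()].
#' @param vc [variance_components()] defining `V = sigma_g2 K + sigma_e2 I`.
#' @param n_reps number of bootstrap replicates.
#' @param seed optional RNG seed.
#' @param mode `"fixedV"` (default) or `"full"`.
#' @param keep_pooled if `TRUE`, also pool all per-marker p-values across
#'   replicates (for calibration QQ checks).
#' @param cost_budget maximum allowed `n_reps * n^3` for full mode.
#' @return Object of class `resampling_run`; its `min_p_dist` feeds
#'   [per_marker_threshold()] directly.
#' @export
parametric_bootstrap <- function(g, k, vc, n_reps = 1000, seed = NULL,
                                 mode = c("fixedV", "full"),
                                 keep_pooled = FALSE, cost_budget = 1e12) {
  mode <- match.arg(mode)
  mt_assert(inherits(g, "genotype_matrix") && g$standardized,
            "g must be a standardized genotype_matrix")
  mt_assert(n_reps >= 1, "n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g$dosages)
  m <- ncol(g$dosages)
  model <- build_covariance_model(k, vc)

  if (mode == "fixedV") {
    xt <- model$V_inv_sqrt %*% g$dosages
    xt <- sweep(xt, 2L, colMeans(xt), "-")
    xt <- sweep(xt, 2L, sqrt(colSums(xt^2)), "/")
    chunk <- max(1L, min(n_reps, as.integer(2e6 / m)))
    maxr <- numeric(0)
    pooled <- if (keep_pooled) vector("list", ceiling(n_reps / chunk)) else NULL
    done <- 0L
    ci <- 0L
    while (done < n_reps) {
      kk <- min(chunk, n_reps - done)
      z <- matrix(stats::rnorm(n * kk), n, kk)
      z <- sweep(z, 2L, colMeans(z), "-")
      z <- sweep(z, 2L, sqrt(colSums(z^2)), "/")
      r <- crossprod(xt, z)               # m x kk correlations
      maxr <- c(maxr, col_max_abs(r))
      if (keep_pooled) {
        ci <- ci + 1L
        pooled[[ci]] <- r_to_pz(as.vector(r), df = n - 2)$p
      }
      done <- done + kk
    }
    min_p <- r_to_pz(maxr, df = n - 2)$p
    min_p <- pmax(min_p, .Machine$double.xmin)
    return(new_resampling_run(min_p, m, "bootstrap-fixedV",
                              pooled_p = if (keep_pooled) unlist(pooled),
                              n_reps = n_reps))
  }

  # full mode: refit variance components per replicate
  cost <- n_reps * as.numeric(n)^3
  if (cost > cost_budget) {
    mt_stop(sprintf(
      "full bootstrap cost n_reps * n^3 = %.3g exceeds budget %.3g; use mode = 'fixedV' or lower n_reps",
      cost, cost_budget))
  }
  cache <- vc_fit_cache(k)
  min_p <- numeric(n_reps)
  pooled <- if (keep_pooled) vector("list", n_reps) else NULL
  for (b in seq_len(n_reps)) {
    ystar <- drop(model$V_sqrt %*% stats::rnorm(n))
    vc_b <- fit_variance_components(ystar, k, method = "REML", cache = cache)
    model_b <- build_covariance_model(k, vc_b)
    scan <- association_scan(ystar, g, model_b)
    min_p[b] <- max(min(scan$pvalue), .Machine$double.xmin)
    if (keep_pooled) pooled[[b]] <- scan$pvalue
    if (b %% 200L == 0L) {
      message(sprintf("full bootstrap: %d / %d replicates", b, n_reps))
    }
  }
  new_resampling_run(min_p, m, "bootstrap-full",
                     pooled_p = if (keep_pooled) unlist(pooled),
                     n_reps = n_reps)
}

#' Naive permutation test under the mixed model
#'
#' Permutes the phenotype uniformly without replacement, refits the
#' variance components on each permuted phenotype (fixed K), and runs the
#' association scan under the refitted model, pooling p-values and
#' recording per-replicate minimum p.  Permutation destroys the alignment
#' between phenotype and relatedness that the mixed model encodes, so under
#' genuine structure the pooled p-values are miscalibrated — this operation
#' exists to demonstrate that failure; the parametric bootstrap is the
#' valid resampling scheme.
#'
#' @param g standardized [genotype_matrix()].
#' @param k [kinship_matrix()].
#' @param y observed [phenotype_vector()] or numeric vector.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional RNG seed.
#' @param refit_vc refit variance components per permutation (default
#'   `TRUE`, the faithful "apply the mixed model to permuted data"
#'   protocol); `FALSE` keeps the model fitted on the observed phenotype.
#' @return Object of class `resampling_run` with pooled p-values.
#' @export
permutation_test <- function(g, k, y, n_perm = 1000, seed = NULL,
                             refit_vc = TRUE) {
  mt_assert(inherits(g, "genotype_matrix") && g$standardized,
            "g must be a standardized genotype_matrix")
  mt_assert(n_perm >= 100, "n_perm must be >= 100")
  yv <- as_phenotype_values(y)
  n <- length(yv)
  mt_assert(nrow(g$dosages) == n, "phenotype length mismatch")
  if (!is.null(seed)) set.seed(seed)
  cache <- vc_fit_cache(k)
  model_obs <- if (!refit_vc) {
    build_covariance_model(k, fit_variance_components(yv, k, cache = cache))
  }
  min_p <- numeric(n_perm)
  pooled <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    yp <- yv[sample.int(n)]
    model_b <- if (refit_vc) {
      build_covariance_model(
        k, fit_variance_components(yp, k, method = "REML", cache = cache))
    } else {
      model_obs
    }
    scan <- suppressWarnings(association_scan(yp, g, model_b))
    min_p[b] <- max(min(scan$pvalue), .Machine$double.xmin)
    pooled[[b]] <- scan$pvalue
  }
  new_resampling_run(min_p, ncol(g$dosages), "permutation",
                     pooled_p = unlist(pooled), n_reps = n_perm)
}

#' Expected-vs-observed quantiles for a QQ plot
#'
#' @param pvals p-values in (0, 1].
#' @return Data frame with `expected` and `observed` columns, both on the
#'   -log10 scale, sorted so points read from smallest to largest
#'   significance; expected quantiles use plotting positions
#'   `(k - 0.5) / N`.
#' @export
qq_report <- function(pvals) {
  pvals <- as.numeric(pvals)
  mt_assert(length(pvals) >= 1, "empty p-value vector")
  mt_assert(all(pvals > 0 & pvals <= 1), "p-values must be in (0, 1]")
  n <- length(pvals)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(sort(pvals)))
}
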