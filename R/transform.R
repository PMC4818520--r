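#' Transform genotypes into the whitened space of the fitted model
#'
#' Multiplies every genotype column by the symmetric inverse square root of
#' the fitted phenotype covariance, then re-centers and re-scales each
#' column to mean 0 and variance 1 (denominator n).  Correlations between
#' the resulting columns are the covariances of the null mixed-model
#' association statistics; with an identity model they reduce to raw
#' genotype correlations.
#'
#' @param g standardized [genotype_matrix()].
#' @param model a `covariance_model` (see [build_covariance_model()]), or
#'   [identity_model()] for the untransformed linear-model baseline.
#' @return Object of class `transformed_genotypes`: `matrix` (n x m, each
#'   column mean 0 variance 1), marker metadata, `transform_tag`.
#' @export
transform_genotypes <- function(g, model) {
  mt_assert(inherits(g, "genotype_matrix"), "not a genotype_matrix")
  mt_assert(g$standardized, "transform_genotypes expects standardized genotypes")
  mt_assert(inherits(model, "covariance_model"), "not a covariance_model")
  mt_assert(nrow(model$V) == nrow(g$dosages),
            "dimension mismatch between genotypes and model")
  xt <- model$V_inv_sqrt %*% g$dosages
  xt <- col_standardize(xt, what = "transformed marker column(s)")
  tag <- if (model$vc$sigma_g2 == 0 && all(model$lambda == model$lambda[1])) {
    "identity"
  } else {
    sprintf("vinv_sqrt_h2_%.4f", model$vc$heritability)
  }
  structure(list(matrix = xt, markers = g$markers,
                 individual_ids = g$individual_ids, transform_tag = tag),
            class = "transformed_genotypes")
}

#' @export
print.transformed_genotypes <- function(x, ...) {
  cat(sprintf("transformed_genotypes: %d x %d (transform: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$transform_tag))
  invisible(x)
}

#' Banded correlation of transformed genotypes
#'
#' Computes, for every marker i and lag d = 1..window, the Pearson
#' correlation between transformed markers i and i-d, provided both lie on
#' the same chromosome; cross-chromosome entries are 0 (statistics on
#' different chromosomes are treated as independent, a conservative
#' assumption once structure has been removed).  This band is the only part
#' of the m x m statistic covariance the sliding-window sampler needs;
#' memory is m * window * 8 bytes.
#'
#' @param t [transform_genotypes()] output.
#' @param window band half-width w >= 1.  A window spanning more markers
#'   than a chromosome holds simply falls back to the full
#'   within-chromosome band.
#' @param noise_floor entries with absolute value below this are treated as
#'   zero.  The default, `2 / sqrt(n)`, is two standard errors of a null
#'   sample correlation: with n individuals every band entry carries
#'   estimation noise of standard deviation about `1/sqrt(n)`, and
#'   conditioning a window of w markers on such noise overfits badly once w
#'   approaches n (the conditional variance collapses spuriously).
#'   Thresholding the band is the standard banding/hard-threshold estimator
#'   for a covariance that is banded in truth — which is exactly the local
#'   linkage-disequilibrium assumption.  Set to 0 to keep the raw sample
#'   correlations.
#' @return Object of class `banded_covariance` with `band` (m x window,
#'   entry `[i, d]` = cor of markers i and i-d), `window`, `chromosomes`,
#'   `marker_ids`, `n`.
#' @export
windowed_correlation <- function(t, window, noise_floor = NULL) {
  mt_assert(inherits(t, "transformed_genotypes"), "not transformed_genotypes")
  window <- as.integer(window)
  mt_assert(window >= 1, "window must be >= 1")
  x <- t$matrix
  n <- nrow(x)
  m <- ncol(x)
  noise_floor <- noise_floor %||% (2 / sqrt(n))
  mt_assert(noise_floor >= 0 && noise_floor < 1,
            "noise_floor must be in [0, 1)")
  chrom <- t$markers$chrom
  band <- matrix(0, m, window)
  for (d in seq_len(min(window, m - 1L))) {
    i <- seq.int(d + 1L, m)
    cs <- colSums(x[, i, drop = FALSE] * x[, i - d, drop = FALSE]) / n
    cs[chrom[i] != chrom[i - d]] <- 0
    cs[abs(cs) < noise_floor] <- 0
    band[i, d] <- pmin(pmax(cs, -1), 1)
  }
  structure(list(band = band, window = window, chromosomes = chrom,
                 marker_ids = t$markers$id, n = n,
                 noise_floor = noise_floor,
                 transform_tag = t$transform_tag),
            class = "banded_covariance")
}

#' @export
print.banded_covariance <- function(x, ...) {
  cat(sprintf("banded_covariance: %d markers, window %d (transform: %s)\n",
              nrow(x$band), x$window, x$transform_tag))
  invisible(x)
}

# In-band correlation between markers i and j (i != j); 0 outside the band
# or across chromosomes.
band_entry <- function(bc, i, j) {
  d <- abs(i - j)
  hi <- pmax(i, j)
  out <- numeric(length(d))
  ok <- d >= 1 & d <= bc$window
  out[ok] <- bc$band[cbind(hi[ok], d[ok])]
  out
}

#' Expand a banded covariance to a dense correlation matrix
#'
#' Intended for small-m exact work (oracle sampling, calibration checks);
#' pairs beyond the band are set to 0 under the local linkage
#' disequilibrium assumption.
#'
#' @param bc a `banded_covariance`.
#' @return m x m correlation matrix.
#' @export
as_dense_covariance <- function(bc) {
  mt_assert(inherits(bc, "banded_covariance"), "not a banded_covariance")
  m <- nrow(bc$band)
  sigma <- diag(m)
  w <- min(bc$window, m - 1L)
  for (d in seq_len(w)) {
    i <- seq.int(d + 1L, m)
    sigma[cbind(i, i - d)] <- bc$band[i, d]
    sigma[cbind(i - d, i)] <- bc$band[i, d]
  }
  sigma
}

#' Compare empirical statistic covariance with genotype correlations
#'
#' Simulates null phenotypes from `N(0, V)` under the fitted model,
#' computes the full association scan for each replicate, and measures the
#' empirical covariance of the statistics across replicates.  Returns the
#' paired differences of that covariance against (a) the correlation of
#' transformed genotypes and (b) the raw genotype correlation, for every
#' marker pair.  Under structure and non-zero heritability the transformed
#' correlations track the statistic covariance while the raw correlations
#' drift away.
#'
#' @param g standardized [genotype_matrix()] (keep m small, a few hundred).
#' @param k [kinship_matrix()].
#' @param vc [variance_components()].
#' @param n_reps number of simulated phenotypes (>= 100; >= 1000 advised).
#' @param seed optional RNG seed.
#' @return List with `diff_transformed`, `diff_raw` (upper-triangle paired
#'   differences), their means and mean absolute values, and the three
#'   matrices.
#' @export
covariance_calibration_check <- function(g, k, vc, n_reps = 1000,
                                         seed = NULL) {
  mt_assert(inherits(g, "genotype_matrix") && g$standardized,
            "g must be a standardized genotype_matrix")
  mt_assert(n_reps >= 100, "n_reps < 100: Monte-Carlo noise would dominate")
  if (!is.null(seed)) set.seed(seed)
  model <- build_covariance_model(k, vc)
  n <- nrow(g$dosages)
  m <- ncol(g$dosages)

  # null phenotypes Y = V^{1/2} Z, then the scan's own transform/centering
  z <- matrix(stats::rnorm(n * n_reps), n, n_reps)
  y <- model$V_sqrt %*% z
  yt <- model$V_inv_sqrt %*% y
  yt <- sweep(yt, 2L, colMeans(yt), "-")
  yt <- sweep(yt, 2L, sqrt(colSums(yt^2)), "/")
  xt <- model$V_inv_sqrt %*% g$dosages
  xt <- sweep(xt, 2L, colMeans(xt), "-")
  xt <- sweep(xt, 2L, sqrt(colSums(xt^2)), "/")
  r <- crossprod(xt, yt)                    # m x n_reps correlations
  s <- matrix(r_to_pz(as.vector(r), df = n - 2)$z, m, n_reps)

  cov_emp <- stats::cov(t(s))
  r_m <- crossprod(xt)                      # unit columns: correlation
  x_raw <- g$dosages
  r_raw <- crossprod(x_raw) / n
  ut <- upper.tri(cov_emp)
  dt <- cov_emp[ut] - r_m[ut]
  dr <- cov_emp[ut] - r_raw[ut]
  list(diff_transformed = dt, diff_raw = dr,
       mean_diff_transformed = mean(dt), mean_diff_raw = mean(dr),
       mean_abs_diff_transformed = mean(abs(dt)),
       mean_abs_diff_raw = mean(abs(dr)),
       cov_empirical = cov_emp, cor_transformed = r_m, cor_raw = r_raw,
       n_reps = n_reps)
}
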