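#' Sampler configuration
#'
#' @param window conditioning window w (number of predecessors).
#' @param n_samples number of replicate statistic vectors s.
#' @param seed RNG seed (`NULL` = use the current stream).
#' @param ridge diagonal regularizer added to a window block whose Cholesky
#'   factorization fails; escalated up to two more times (x100 each).
#' @param min_conditional_var floor for the conditional variance, so
#'   perfectly predicted markers (e.g. exact duplicates) still receive a
#'   valid, slightly conservative draw.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(window = 1000, n_samples = 1e5, seed = NULL,
                           ridge = 1e-8, min_conditional_var = 1e-8) {
  mt_assert(window >= 1, "window must be >= 1")
  mt_assert(n_samples >= 1, "n_samples must be >= 1")
  structure(list(window = as.integer(window),
                 n_samples = as.integer(n_samples), seed = seed,
                 ridge = ridge, min_conditional_var = min_conditional_var),
            class = "sampler_config")
}

new_null_minp <- function(min_p, m, provenance, n_samples = length(min_p)) {
  mt_assert(all(min_p > 0 & min_p <= 1), "min_p values must be in (0, 1]")
  structure(list(min_p = min_p, sorted = sort(min_p), m = as.integer(m),
                 n_samples = as.integer(n_samples), provenance = provenance),
            class = "null_minp")
}

#' @export
print.null_minp <- function(x, ...) {
  cat(sprintf("null_minp (%s): %d replicates over %d markers; median min-p %.3g\n",
              x$provenance, x$n_samples, x$m, stats::median(x$min_p)))
  invisible(x)
}

# Solve a %*% c = b for a symmetric "correlation-like" block that may be
# rank-deficient (w >= n gives exactly singular Gram blocks) or slightly
# indefinite (a hard-thresholded band).  Fast path: plain Cholesky.
# Fallback: eigendecomposition with the spectrum clipped at
# tol * max(eigenvalue), i.e. the pseudo-inverse on the retained subspace.
solve_psd <- function(a, b, tol = 1e-8) {
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
  }
  e <- eigen(a, symmetric = TRUE)
  keep <- e$values > max(e$values[1], 0) * max(tol, 1e-12)
  if (!any(keep)) return(rep(0, length(b)))
  v <- e$vectors[, keep, drop = FALSE]
  drop(v %*% (crossprod(v, b) / e$values[keep]))
}

#' Sample null statistics by sliding-window conditional Gaussians
#'
#' Draws `n_samples` replicate vectors of null association statistics from
#' `MVN(0, Sigma)` where `Sigma` is the banded correlation of transformed
#' genotypes, using the chain-rule factorization: within each chromosome,
#' statistic i is drawn conditionally on the previous `w` statistics,
#' `S_i | S_{i-w..i-1} ~ N(c' s_prev, 1 - c' rho)`.  Chromosomes are
#' independent.  All replicates advance simultaneously and only the running
#' maximum absolute statistic per replicate is kept, from which each
#' replicate's minimum pointwise p-value `2 * pnorm(-max|S|)` is computed.
#'
#' Two details make the chain well-posed when the band is an *estimated*
#' (hence not exactly self-consistent) covariance: marker i is conditioned
#' only on predecessors with non-zero band correlation to it (the local-LD
#' support; see the `noise_floor` argument of [windowed_correlation()]),
#' and the conditional coefficients are solved against the chain's own
#' realized covariance of the window with the band entries as targets, with
#' the conditional variance set so every marginal is exactly 1.  For a band
#' that is exactly a correlation matrix restriction (e.g. the full Gram at
#' `window >= m - 1`) this reduces to the textbook conditional MVN sampler;
#' for a thresholded band it yields a valid Gaussian law that matches the
#' band on its support instead of accumulating variance drift.
#'
#' @param band a [windowed_correlation()] result.
#' @param cfg a [sampler_config()]; the effective window is
#'   `min(band$window, cfg$window)`.
#' @return Object of class `null_minp` with provenance `"multitrans"`.
#' @examples
#' g <- simulate_genotypes(synth_config(n_individuals = 60, n_markers = 100,
#'                                      seed = 1))
#' gs <- standardize(filter_markers(g))
#' k <- compute_kinship(gs)
#' tg <- transform_genotypes(gs, build_covariance_model(
#'   k, variance_components(0.5, 0.5)))
#' band <- windowed_correlation(tg, window = 20)
#' minp <- sample_null_statistics(band, sampler_config(window = 20,
#'                                                     n_samples = 2000,
#'                                                     seed = 7))
#' per_marker_threshold(minp, alpha = 0.05)
#' @export
sample_null_statistics <- function(band, cfg = sampler_config()) {
  mt_assert(inherits(band, "banded_covariance"), "not a banded_covariance")
  mt_assert(inherits(cfg, "sampler_config"), "not a sampler_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  w <- min(band$window, cfg$window)
  s <- cfg$n_samples
  m <- nrow(band$band)
  chrom <- chrom_factor(band$chromosomes)

  # Pass 1: conditional coefficients per marker.  These depend only on the
  # band (and the chain's realized covariance, maintained alongside), not
  # on the replicate draws, so they are computed once.
  plans <- lapply(levels(chrom), function(ch) {
    idx <- which(chrom == ch)
    creal <- diag(w)             # realized model covariance of buffer rows
    buf_marker <- rep(NA_integer_, w)
    ptr <- 0L
    plan <- vector("list", length(idx))
    for (t in seq_along(idx)) {
      i <- idx[t]
      rows <- integer(0)
      if (t > 1L) {
        rows <- which(!is.na(buf_marker))
        mk <- buf_marker[rows]
        # correlations looked up in buffer row order: no reordering copies
        rho <- band_entry(band, rep(i, length(mk)), mk)
        # condition only on predecessors actually correlated with marker i:
        # the band support is the local-LD neighbourhood, and conditioning
        # a w-dimensional system on n-sample correlation noise overfits
        # once w approaches n
        sel <- which(rho != 0)
        rows <- rows[sel]
        rho <- rho[sel]
      }
      newrow <- numeric(w)
      cfull <- NULL
      condvar <- 1
      if (length(rows)) {
        cvec <- solve_psd(creal[rows, rows, drop = FALSE], rho,
                          tol = cfg$ridge)
        crho <- sum(cvec * rho)
        if (crho > 1 - cfg$min_conditional_var) {
          # inconsistent targets (thresholding artefacts): shrink towards
          # the feasible cone so the marginal stays at 1
          cvec <- cvec * sqrt((1 - cfg$min_conditional_var) / crho)
          crho <- 1 - cfg$min_conditional_var
        }
        condvar <- max(1 - crho, cfg$min_conditional_var)
        cfull <- numeric(w)
        cfull[rows] <- cvec
        newrow <- drop(creal %*% cfull)   # realized Cov(S_i, window)
      }
      ptr <- if (ptr == w) 1L else ptr + 1L
      buf_marker[ptr] <- i
      creal[ptr, ] <- newrow
      creal[, ptr] <- newrow
      creal[ptr, ptr] <- 1
      plan[[t]] <- list(cfull = cfull, sd = sqrt(condvar))
    }
    plan
  })

  # Pass 2: advance all replicates through the chain, chunked so the
  # w x chunk ring buffer stays within a fixed memory budget.
  chunk <- max(1L, min(s, as.integer(5e7 / w)))
  maxabs <- numeric(0)
  done <- 0L
  while (done < s) {
    sc <- min(chunk, s - done)
    mx <- numeric(sc)
    for (plan in plans) {
      buf <- matrix(0, w, sc)    # ring buffer of the last w statistic rows
      ptr <- 0L
      for (t in seq_along(plan)) {
        p <- plan[[t]]
        draw <- p$sd * stats::rnorm(sc)
        if (!is.null(p$cfull)) {
          draw <- draw + drop(crossprod(p$cfull, buf))
        }
        ptr <- if (ptr == w) 1L else ptr + 1L
        buf[ptr, ] <- draw
        mx <- pmax(mx, abs(draw))
      }
    }
    maxabs <- c(maxabs, mx)
    done <- done + sc
  }
  min_p <- 2 * stats::pnorm(-maxabs)
  min_p <- pmax(min_p, .Machine$double.xmin)
  new_null_minp(min_p, m, "multitrans", s)
}

#' Sample null statistics from the dense covariance (exact oracle)
#'
#' Full-covariance Cholesky sampling of `MVN(0, Sigma)`; the reference
#' implementation against which the sliding-window sampler is validated.
#' Dense, so limited to m <= 5000.
#'
#' @param sigma an m x m correlation matrix, or a `banded_covariance`
#'   (expanded with zeros outside the band).
#' @param cfg a [sampler_config()] (its `window` is ignored).
#' @return Object of class `null_minp` with provenance `"exact-mvn"`.
#' @export
sample_exact_mvn <- function(sigma, cfg = sampler_config()) {
  mt_assert(inherits(cfg, "sampler_config"), "not a sampler_config")
  if (inherits(sigma, "banded_covariance")) sigma <- as_dense_covariance(sigma)
  sigma <- as.matrix(sigma)
  m <- nrow(sigma)
  mt_assert(m <= 5000, "dense sampler limited to m <= 5000")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  # factor L with L %*% t(L) = Sigma: Cholesky when PD, else eigen factor
  # with the spectrum clipped at 0 (exact for rank-deficient Grams)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  lmat <- if (!is.null(ch)) {
    t(ch)
  } else {
    e <- eigen(sigma, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  }
  s <- cfg$n_samples
  chunk <- max(1L, min(s, as.integer(2e6 / m)))
  maxabs <- numeric(0)
  done <- 0L
  while (done < s) {
    k <- min(chunk, s - done)
    z <- matrix(stats::rnorm(m * k), m, k)
    x <- lmat %*% z
    maxabs <- c(maxabs, col_max_abs(x))
    done <- done + k
  }
  min_p <- pmax(2 * stats::pnorm(-maxabs), .Machine$double.xmin)
  new_null_minp(min_p, m, "exact-mvn", s)
}
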