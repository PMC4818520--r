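#' Construct a variance-components object
#'
#' Holds the genetic and residual variances of the mixed model
#' `y ~ N(mu 1, sigma_g2 K + sigma_e2 I)` and the derived narrow-sense
#' heritability `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param sigma_g2,sigma_e2 non-negative variances, not both zero.
#' @param loglik objective value at the optimum (if fitted).
#' @param method `"REML"`, `"ML"`, or `"fixed"` for user-specified values.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(sigma_g2, sigma_e2, loglik = NA_real_,
                                method = "fixed") {
  mt_assert(sigma_g2 >= 0 && sigma_e2 >= 0, "variances must be >= 0")
  mt_assert(sigma_g2 + sigma_e2 > 0, "sigma_g2 + sigma_e2 must be > 0")
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 heritability = sigma_g2 / (sigma_g2 + sigma_e2),
                 loglik = loglik, method = method),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (%s): sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$method, x$sigma_g2, x$sigma_e2, x$heritability))
  invisible(x)
}

# Spectral machinery reused across fits on a shared K: eigen(K) for ML and
# the covariance model, eigen of the intercept-projected S K S (n-1
# informative dimensions) for REML.  Computing these once makes
# per-replicate refits in the bootstrap/permutation loops O(n^2).
vc_fit_cache <- function(k) {
  mt_assert(inherits(k, "kinship_matrix"), "not a kinship_matrix")
  kv <- k$values
  n <- nrow(kv)
  ek <- eigen(kv, symmetric = TRUE)
  ek$values <- pmax(ek$values, 0)
  # Householder reflector mapping e1 to 1/sqrt(n): its remaining n-1
  # columns are an orthonormal basis of the intercept's orthogonal
  # complement (robust even when K is rank-deficient).
  w <- rep(1 / sqrt(n), n)
  w[1] <- w[1] - 1
  H <- diag(n) - 2 * tcrossprod(w) / sum(w^2)
  B <- H[, -1, drop = FALSE]
  eb <- eigen(crossprod(B, kv %*% B), symmetric = TRUE)
  list(n = n, U = ek$vectors, lambda = ek$values,
       W = B %*% eb$vectors,
       lambda_r = pmax(eb$values, 0))
}

# Profiled objectives over delta = sigma_e2 / sigma_g2.
reml_obj <- function(logdelta, eta2, lambda_r, nq) {
  d <- exp(logdelta)
  lv <- lambda_r + d
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(sum(eta2 / lv)) -
           sum(log(lv)))
}

ml_obj <- function(logdelta, omega, xtilde, lambda, n) {
  d <- exp(logdelta)
  lv <- lambda + d
  mu <- sum(xtilde * omega / lv) / sum(xtilde^2 / lv)
  r2 <- (omega - mu * xtilde)^2
  0.5 * (n * log(n / (2 * pi)) - n - n * log(sum(r2 / lv)) - sum(log(lv)))
}

#' Fit mixed-model variance components
#'
#' Maximizes the restricted (default) or full likelihood of
#' `y ~ N(mu 1, sigma_g2 K + sigma_e2 I)` over the single ratio
#' `delta = sigma_e2/sigma_g2` after one eigendecomposition of K
#' (EMMA-style profiling).  The profiled objective is evaluated on a
#' 100-point grid of `log(delta)` over `[-10, 10]` and the best bracket is
#' refined by Brent's method to 1e-6.  A boundary optimum is reported as
#' heritability 0 or 1 with a warning.
#'
#' @param y [phenotype_vector()] or numeric vector.
#' @param k [kinship_matrix()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param cache optional result of an internal spectral precomputation on
#'   `k`, for repeated fits against the same kinship.
#' @return A [variance_components()] with the objective value attached.
#' @examples
#' g <- simulate_genotypes(synth_config(n_individuals = 80, n_markers = 200,
#'                                      seed = 1))
#' k <- compute_kinship(standardize(filter_markers(g)))
#' y <- simulate_phenotype(k, h2 = 0.5, seed = 2)
#' fit_variance_components(y, k)
#' @export
fit_variance_components <- function(y, k, method = c("REML", "ML"),
                                    cache = NULL) {
  method <- match.arg(method)
  yv <- as_phenotype_values(y)
  mt_assert(all(is.finite(yv)), "phenotype must be finite")
  mt_assert(stats::var(yv) > 0, "phenotype has zero variance")
  cache <- cache %||% vc_fit_cache(k)
  n <- cache$n
  mt_assert(length(yv) == n, "phenotype length does not match kinship")

  if (method == "REML") {
    eta2 <- drop(crossprod(cache$W, yv))^2
    nq <- n - 1
    obj <- function(ld) reml_obj(ld, eta2, cache$lambda_r, nq)
  } else {
    omega <- drop(crossprod(cache$U, yv))
    xtilde <- drop(crossprod(cache$U, rep(1, n)))
    obj <- function(ld) ml_obj(ld, omega, xtilde, cache$lambda, n)
  }

  grid <- seq(-10, 10, length.out = 100)
  vals <- vapply(grid, obj, 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
  ld <- opt$maximum
  if (obj(ld) < vals[i]) ld <- grid[i]  # guard against a flat refine
  boundary <- ld <= grid[1] + 1e-6 || ld >= grid[length(grid)] - 1e-6
  if (boundary) {
    warning(sprintf(
      "variance-ratio optimum at the search boundary (log delta = %.2f); heritability reported as %s",
      ld, if (ld < 0) "~1" else "~0"))
  }
  delta <- exp(ld)

  if (method == "REML") {
    sg2 <- sum(eta2 / (cache$lambda_r + delta)) / (n - 1)
  } else {
    omega <- drop(crossprod(cache$U, yv))
    xtilde <- drop(crossprod(cache$U, rep(1, n)))
    lv <- cache$lambda + delta
    mu <- sum(xtilde * omega / lv) / sum(xtilde^2 / lv)
    sg2 <- sum((omega - mu * xtilde)^2 / lv) / n
  }
  variance_components(sigma_g2 = sg2, sigma_e2 = delta * sg2,
                      loglik = obj(ld), method = method)
}

#' Build the fitted phenotype covariance and its inverse square root
#'
#' Computes `V = sigma_g2 K + sigma_e2 I` and the symmetric inverse square
#' root `V^{-1/2} = U diag(1/sqrt(sigma_g2 lambda_i + sigma_e2)) t(U)` from
#' the eigendecomposition of K (eigenvalues clipped at 0).  The symmetric
#' root is unique, which simplifies testing; any factor with
#' `t(A) A = V^{-1}` would yield identical transformed-genotype
#' correlations.
#'
#' @param k [kinship_matrix()].
#' @param vc [variance_components()].
#' @return Object of class `covariance_model` with `V`, `V_inv_sqrt`,
#'   `V_sqrt`, the cached eigendecomposition, and `vc`.
#' @export
build_covariance_model <- function(k, vc) {
  mt_assert(inherits(k, "kinship_matrix"), "not a kinship_matrix")
  mt_assert(inherits(vc, "variance_components"), "not variance_components")
  ek <- eigen(k$values, symmetric = TRUE)
  lambda <- pmax(ek$values, 0)
  d <- vc$sigma_g2 * lambda + vc$sigma_e2
  if (any(d <= 1e-12)) {
    mt_stop("singular fitted covariance: sigma_g2 * lambda + sigma_e2 <= 1e-12",
            "mt_numerical_error")
  }
  U <- ek$vectors
  vis <- U %*% (t(U) / sqrt(d))       # U diag(1/sqrt(d)) U'
  vis <- (vis + t(vis)) / 2
  vsq <- U %*% (t(U) * sqrt(d))
  vsq <- (vsq + t(vsq)) / 2
  v <- U %*% (t(U) * d)
  structure(list(V = (v + t(v)) / 2, V_inv_sqrt = vis, V_sqrt = vsq,
                 U = U, lambda = lambda, d = d, vc = vc,
                 individual_ids = k$individual_ids),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("covariance_model: n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)\n",
              nrow(x$V), x$vc$sigma_g2, x$vc$sigma_e2, x$vc$heritability))
  invisible(x)
}

#' Identity covariance model
#'
#' Convenience model with `V = I`, under which the mixed-model scan reduces
#' to ordinary linear regression and transformed correlations equal raw
#' genotype correlations.
#'
#' @param n number of individuals.
#' @return A `covariance_model`.
#' @export
identity_model <- function(n) {
  k <- kinship_matrix(diag(n))
  build_covariance_model(k, variance_components(0, 1))
}

#' Mixed-model association scan
#'
#' Transforms phenotype and genotypes by `V^{-1/2}`, centers both in the
#' transformed space (absorbing the intercept), and computes for each
#' marker the generalized least-squares effect and its standardized
#' statistic.  The reported statistic is on the z scale: the marginal
#' p-value is computed from the exact Student-t null of the
#' transformed-space correlation (df = n - 2) and mapped back through the
#' standard-normal quantile, so `pvalue == 2 * (1 - pnorm(abs(stat)))`
#' holds exactly while per-marker p-values remain calibrated at finite n.
#'
#' @param y [phenotype_vector()] or numeric vector.
#' @param g standardized [genotype_matrix()].
#' @param model [build_covariance_model()] output (or [identity_model()]).
#' @return Data frame with one row per marker: `id`, `chrom`, `pos`,
#'   `beta`, `stat`, `pvalue`.
#' @export
association_scan <- function(y, g, model) {
  mt_assert(inherits(g, "genotype_matrix"), "not a genotype_matrix")
  mt_assert(g$standardized, "association_scan expects standardized genotypes")
  mt_assert(inherits(model, "covariance_model"), "not a covariance_model")
  yv <- as_phenotype_values(y)
  n <- length(yv)
  mt_assert(nrow(g$dosages) == n && nrow(model$V) == n,
            "dimension mismatch between phenotype, genotypes and model")

  yt <- drop(model$V_inv_sqrt %*% yv)
  yt <- yt - mean(yt)
  sy <- sqrt(mean(yt^2))
  mt_assert(sy > 1e-12, "phenotype has zero variance after transformation",
            "mt_numerical_error")
  xt <- model$V_inv_sqrt %*% g$dosages
  xt <- sweep(xt, 2L, colMeans(xt), "-")
  ssx <- colSums(xt^2)
  degenerate <- ssx < 1e-12 * n
  if (any(degenerate)) {
    warning(sprintf("%d marker(s) with zero variance after transformation; statistic set to 0, p to 1",
                    sum(degenerate)))
    ssx[degenerate] <- 1
  }
  num <- drop(crossprod(xt, yt))
  r <- num / (sqrt(ssx) * sqrt(sum(yt^2)))
  pz <- r_to_pz(r, df = n - 2)
  beta <- num / ssx
  stat <- pz$z
  pval <- pz$p
  stat[degenerate] <- 0
  pval[degenerate] <- 1
  beta[degenerate] <- 0
  data.frame(id = g$markers$id, chrom = g$markers$chrom,
             pos = g$markers$pos, beta = beta, stat = stat, pvalue = pval,
             stringsAsFactors = FALSE)
}
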