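# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers (and the command-line wrapper) can map error
# families to exit codes: io, validation, numerical.
mt_stop <- function(msg, class = "mt_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "mt_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

mt_assert <- function(cond, msg, class = "mt_validation_error") {
  if (!isTRUE(cond)) mt_stop(msg, class)
  invisible(TRUE)
}

# Population (denominator n) column standardization used everywhere: with
# this convention the correlation of two standardized columns is their
# inner product divided by n.
col_standardize <- function(x, tol = 1e-12, what = "column") {
  n <- nrow(x)
  cm <- colMeans(x)
  x <- sweep(x, 2L, cm, "-")
  v <- colMeans(x^2)
  bad <- which(v < tol)
  if (length(bad)) {
    mt_stop(sprintf("zero-variance %s: %s", what,
                    paste(bad, collapse = ", ")),
            "mt_numerical_error")
  }
  sweep(x, 2L, sqrt(v), "/")
}

# Map a correlation-scale statistic to its exact two-sided p-value under the
# marginal Student-t null with df degrees of freedom, and to the equivalent
# z-score (probability integral transform).  Keeping the statistic on the z
# scale makes the MVN machinery, which assumes unit-variance normal margins,
# consistent with the finite-sample null of the scan.
r_to_pz <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  # log-scale tail to keep precision for extreme statistics
  logp_half <- stats::pt(abs(tt), df = df, lower.tail = FALSE, log.p = TRUE)
  p <- 2 * exp(logp_half)
  p <- pmin(p, 1)
  # P(Z > |z|) = p/2  =>  |z| = -qnorm(log(p/2), log.p = TRUE)
  z <- sign(r) * (-stats::qnorm(logp_half, log.p = TRUE))
  list(p = p, z = z, t = tt)
}

# Column-wise max of |A| without apply() overhead.
col_max_abs <- function(a) {
  a <- abs(a)
  idx <- max.col(t(a), ties.method = "first")
  a[cbind(idx, seq_len(ncol(a)))]
}

chrom_factor <- function(chromosomes) {
  factor(chromosomes, levels = unique(chromosomes))
}
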