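#' Construct or validate a kinship matrix
#'
#' Symmetric positive semi-definite genetic relatedness matrix K.  A matrix
#' with asymmetry above 1e-6 is symmetrized as `(K + t(K))/2` with a
#' warning; eigenvalues below -1e-8 are rejected, values in `(-1e-8, 0)`
#' are tolerated and clipped to zero downstream.
#'
#' @param values n x n numeric matrix.
#' @param individual_ids length-n identifiers.
#' @param n_markers_used number of markers behind the estimate (if known).
#' @return Object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(values, individual_ids = NULL,
                           n_markers_used = NA_integer_) {
  values <- as.matrix(values)
  n <- nrow(values)
  mt_assert(n >= 2 && ncol(values) == n, "kinship must be square, n >= 2")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-6) {
    warning(sprintf("kinship asymmetry %.3g; symmetrizing as (K + t(K))/2",
                    asym))
  }
  values <- (values + t(values)) / 2
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  mt_assert(min(ev) > -1e-8,
            sprintf("kinship is not PSD (min eigenvalue %.3g)", min(ev)),
            "mt_numerical_error")
  mt_assert(all(diag(values) > 0), "kinship diagonal must be positive")
  individual_ids <- individual_ids %||% rownames(values) %||%
    paste0("ind", seq_len(n))
  dimnames(values) <- list(individual_ids, individual_ids)
  structure(list(values = values,
                 individual_ids = as.character(individual_ids),
                 n_markers_used = as.integer(n_markers_used)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("kinship_matrix: %d individuals (from %s markers)\n", n,
              ifelse(is.na(x$n_markers_used), "?", x$n_markers_used)))
  cat(sprintf("  diag mean %.3f; off-diag range [%.3f, %.3f]\n",
              mean(diag(x$values)), min(off), max(off)))
  invisible(x)
}

#' Estimate the kinship matrix from standardized genotypes
#'
#' The realized genetic relationship matrix `K = X t(X) / m` on the n x m
#' standardized dosage matrix; its mean diagonal is approximately 1.  Any
#' estimator can be substituted by supplying a user kinship file: the
#' method is valid for an arbitrary PSD K because the variance components
#' are refit under whichever K is used.
#'
#' @param g standardized [genotype_matrix()].
#' @return A [kinship_matrix()].
#' @export
compute_kinship <- function(g) {
  mt_assert(inherits(g, "genotype_matrix"), "not a genotype_matrix")
  mt_assert(g$standardized,
            "kinship is computed on standardized genotypes; call standardize(g)")
  m <- ncol(g$dosages)
  k <- tcrossprod(g$dosages) / m
  kinship_matrix(k, g$individual_ids, n_markers_used = m)
}

#' Summarize the off-diagonal relatedness distribution
#'
#' Histogram counts and quantiles of the n(n-1)/2 upper-triangle entries,
#' the standard display for comparing the amount of relatedness across
#' panels.
#'
#' @param k a [kinship_matrix()].
#' @param bins number of histogram bins.
#' @return List with `breaks`, `counts`, `min`, `median`, `max`,
#'   `quartiles`.
#' @export
kinship_heatmap_summary <- function(k, bins = 30) {
  mt_assert(inherits(k, "kinship_matrix"), "not a kinship_matrix")
  off <- k$values[upper.tri(k$values)]
  mt_assert(length(off) >= 1, "need n >= 2 individuals")
  rng <- range(off)
  if (rng[1] == rng[2]) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    counts <- length(off)
  } else {
    h <- hist(off, breaks = bins, plot = FALSE)
    breaks <- h$breaks
    counts <- h$counts
  }
  list(breaks = breaks, counts = counts,
       min = min(off), median = stats::median(off), max = max(off),
       quartiles = stats::quantile(off, c(0.25, 0.5, 0.75), names = FALSE))
}

#' Read a square text kinship matrix
#'
#' @param path whitespace-delimited n x n square matrix file.
#' @return A [kinship_matrix()].
#' @export
read_kinship <- function(path) {
  mt_assert(file.exists(path), sprintf("file not found: %s", path),
            "mt_io_error")
  vals <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(vals) <- NULL
  kinship_matrix(vals)
}

#' Write a kinship matrix as square whitespace-delimited text
#'
#' @param k a [kinship_matrix()].
#' @param path output file.
#' @export
write_kinship <- function(k, path) {
  mt_assert(inherits(k, "kinship_matrix"), "not a kinship_matrix")
  utils::write.table(format(k$values, digits = 17), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
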