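#' Run the full per-marker threshold pipeline
#'
#' Chains the stages: filter raw genotypes, standardize, estimate (or load)
#' the kinship matrix, fit variance components, build the fitted
#' covariance, transform genotypes, compute the within-window correlation
#' band, sample null statistics, and turn the sampled minimum p-values into
#' a per-marker threshold.  When `out_dir` is given, intermediates and a
#' reproducibility manifest (all parameters, seed, input checksums, package
#' version) are written there as plain text/JSON.
#'
#' @param genotypes raw [genotype_matrix()] or a path readable by
#'   [read_genotypes()].
#' @param phenotype [phenotype_vector()], numeric vector, or a path
#'   readable by [read_phenotype()].
#' @param kinship optional [kinship_matrix()] or path; estimated from the
#'   filtered standardized genotypes when omitted.
#' @param window sliding-window size (markers).
#' @param n_samples MVN sampling replicates.
#' @param alpha family-wise significance level.
#' @param seed RNG seed for the sampler.
#' @param maf_min,missing_max marker filters, see [filter_markers()].
#' @param method variance-component objective, `"REML"` or `"ML"`.
#' @param out_dir optional output directory.
#' @param verbose emit progress messages.
#' @return List with `threshold` ([per_marker_threshold()] result), `vc`,
#'   `minp`, `band`, `n`, `m`, and `manifest`.
#' @examples
#' g <- simulate_genotypes(synth_config(n_individuals = 60, n_markers = 150,
#'                                      seed = 1))
#' k <- compute_kinship(standardize(filter_markers(g)))
#' y <- simulate_phenotype(k, h2 = 0.5, seed = 2)
#' res <- run_multitrans(g, y, window = 30, n_samples = 5000, seed = 3,
#'                       verbose = FALSE)
#' res$threshold
#' @export
run_multitrans <- function(genotypes, phenotype, kinship = NULL,
                           window = 1000, n_samples = 1e5, alpha = 0.05,
                           seed = NULL, maf_min = 0.05, missing_max = 0.10,
                           method = "REML", out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  inputs <- list()
  if (is.character(genotypes)) {
    inputs$genotypes <- genotypes
    genotypes <- read_genotypes(genotypes)
  }
  if (is.character(phenotype)) {
    inputs$phenotype <- phenotype
    phenotype <- read_phenotype(phenotype)
  }
  if (is.character(kinship)) {
    inputs$kinship <- kinship
    kinship <- read_kinship(kinship)
  }

  g <- filter_markers(genotypes, maf_min = maf_min,
                      missing_max = missing_max)
  gs <- standardize(g)
  n <- nrow(gs$dosages)
  m <- ncol(gs$dosages)
  say("panel after filtering: n = %d individuals, m = %d markers", n, m)

  k <- kinship %||% compute_kinship(gs)
  vc <- fit_variance_components(phenotype, k, method = method)
  say("fitted %s variance components: h2 = %.3f (sigma_g2 = %.4g, sigma_e2 = %.4g)",
      vc$method, vc$heritability, vc$sigma_g2, vc$sigma_e2)

  model <- build_covariance_model(k, vc)
  tg <- transform_genotypes(gs, model)
  band <- windowed_correlation(tg, window)
  minp <- sample_null_statistics(
    band, sampler_config(window = window, n_samples = n_samples,
                         seed = seed))
  thr <- per_marker_threshold(minp, alpha)
  say("per-marker threshold at alpha = %g: %.4g (mc_se %.2g; window %d, s = %d)",
      alpha, thr$per_marker_threshold, thr$mc_se, window, n_samples)

  manifest <- list(
    subcommand = "run",
    parameters = list(window = window, n_samples = n_samples,
                      alpha = alpha, seed = seed, maf_min = maf_min,
                      missing_max = missing_max, method = method),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    results = list(alpha = alpha,
                   per_marker_threshold = thr$per_marker_threshold,
                   mc_se = thr$mc_se, heritability = vc$heritability,
                   sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                   n = n, m = m, window = window, n_samples = n_samples,
                   seed = seed),
    package_version = as.character(utils::packageVersion("multitrans")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest$results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_kinship(k, file.path(out_dir, "kinship.txt"))
    utils::write.table(
      data.frame(min_p = minp$min_p),
      file.path(out_dir, "min_p.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(threshold = thr, vc = vc, minp = minp, band = band, kinship = k,
       n = n, m = m, manifest = manifest)
}
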