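# Shared fixtures built in code: small synthetic panels and a tiny
# genotype file writer used by the I/O tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_panel <- function(n = 80, m = 200, fst = 0.2, ld_rho = 0.8,
                       n_populations = 2, chromosomes = 2, seed = 101) {
  cfg <- synth_config(n_individuals = n, n_markers = m,
                      n_populations = n_populations, fst = fst,
                      ld_rho = ld_rho, chromosomes = chromosomes,
                      seed = seed)
  g <- simulate_genotypes(cfg)
  gs <- standardize(filter_markers(g))
  k <- compute_kinship(gs)
  list(raw = g, std = gs, kinship = k, cfg = cfg)
}

write_toy_genotype_file <- function(path,
                                    lines = c(
                                      "chr1\tsnp1\t100\tA\t0\t1",
                                      "chr1\tsnp2\t200\tA\t2\t1",
                                      "chr2\tsnp3\t50\tA\t1\t0")) {
  writeLines(lines, path)
  path
}

# Deterministic "identity-like" banded covariance for sampler tests.
indep_band <- function(m, window, n = 1000L) {
  structure(list(band = matrix(0, m, window), window = as.integer(window),
                 chromosomes = rep("chr1", m),
                 marker_ids = paste0("s", seq_len(m)), n = n,
                 noise_floor = 0, transform_tag = "identity"),
            class = "banded_covariance")
}

# AR(1)-banded covariance: exactly consistent, analytically known.
ar1_band <- function(m, window, rho) {
  band <- matrix(0, m, window)
  for (d in seq_len(min(window, m - 1))) {
    band[(d + 1):m, d] <- rho^d
  }
  structure(list(band = band, window = as.integer(window),
                 chromosomes = rep("chr1", m),
                 marker_ids = paste0("s", seq_len(m)), n = 10000L,
                 noise_floor = 0, transform_tag = "ar1"),
            class = "banded_covariance")
}
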