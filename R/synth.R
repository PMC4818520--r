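#' Configuration for the synthetic genotype generator
#'
#' The generator produces the two features real panels contribute to the
#' multiple-testing problem: population structure (a kinship matrix far
#' from identity, controlled by `fst`) and local linkage disequilibrium
#' (controlled by `ld_rho`).  Allele frequencies follow the
#' Balding-Nichols model; haplotypes follow a first-order Markov copying
#' process along each chromosome, giving geometric LD decay.
#'
#' @param n_individuals number of individuals (assigned to populations
#'   round-robin).
#' @param n_markers total markers, split evenly across chromosomes.
#' @param n_populations number of diverged populations.
#' @param fst divergence parameter F in `[0, 1)`; 0 means a single shared
#'   allele frequency.
#' @param ld_rho probability that an adjacent marker copies the previous
#'   haplotype allele, in `[0, 1)`.
#' @param maf_range range of the ancestral allele frequency (uniform).
#' @param chromosomes number of chromosomes.
#' @param seed RNG seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 100, n_markers = 1000,
                         n_populations = 2, fst = 0.15, ld_rho = 0.7,
                         maf_range = c(0.1, 0.5), chromosomes = 2,
                         seed = NULL) {
  mt_assert(n_individuals >= 2 && n_markers >= 1, "need n >= 2, m >= 1")
  mt_assert(fst >= 0 && fst < 1, "fst must be in [0, 1)")
  mt_assert(ld_rho >= 0 && ld_rho < 1, "ld_rho must be in [0, 1)")
  mt_assert(length(maf_range) == 2 && maf_range[1] > 0 &&
              maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
            "maf_range must be (low, high) within (0, 0.5]")
  mt_assert(n_populations >= 1, "n_populations must be >= 1")
  mt_assert(chromosomes >= 1 && chromosomes <= n_markers,
            "chromosomes must be in [1, n_markers]")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 n_populations = as.integer(n_populations),
                 fst = fst, ld_rho = ld_rho, maf_range = maf_range,
                 chromosomes = as.integer(chromosomes), seed = seed),
            class = "synth_config")
}

#' Simulate a structured genotype panel with local LD
#'
#' Balding-Nichols allele frequencies: an ancestral frequency
#' `p0 ~ U(maf_range)` per marker and, for `fst = F > 0`, per-population
#' frequencies `~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`.  Each individual
#' carries two haplotypes per chromosome; the first marker is drawn
#' Bernoulli at the population frequency and each subsequent marker copies
#' the previous allele with probability `ld_rho`, otherwise redraws — a
#' first-order Markov chain whose allele correlation decays geometrically
#' with distance.  Dosage is the haplotype sum, in `{0, 1, 2}`.
#'
#' @param cfg a [synth_config()].
#' @return A raw [genotype_matrix()]; the population assignment is attached
#'   as attribute `"population"`.
#' @export
simulate_genotypes <- function(cfg) {
  mt_assert(inherits(cfg, "synth_config"), "not a synth_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_individuals
  m <- cfg$n_markers
  npop <- cfg$n_populations
  pop <- rep_len(seq_len(npop), n)

  p0 <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  freq <- if (cfg$fst > 0 && npop > 1) {
    a <- p0 * (1 - cfg$fst) / cfg$fst
    b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
    fr <- matrix(0, npop, m)
    for (p in seq_len(npop)) fr[p, ] <- stats::rbeta(m, a, b)
    pmin(pmax(fr, 0.005), 0.995)   # guard fixed alleles
  } else {
    matrix(rep(p0, each = npop), npop, m)
  }

  chrom_id <- rep(seq_len(cfg$chromosomes),
                  length.out = 0)  # placeholder, built below
  per_chrom <- diff(round(seq(0, m, length.out = cfg$chromosomes + 1)))
  chrom_id <- rep(seq_len(cfg$chromosomes), times = per_chrom)
  pos <- unlist(lapply(per_chrom, function(mc) {
    cumsum(sample(1000:5000, mc, replace = TRUE))
  }), use.names = FALSE)

  pf <- freq[pop, , drop = FALSE]  # n x m per-individual frequencies
  dos <- matrix(0, n, m)
  for (h in 1:2) {
    hap <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      fresh <- stats::rbinom(n, 1L, pf[, j])
      if (j > 1L && chrom_id[j] == chrom_id[j - 1L] && cfg$ld_rho > 0) {
        copy <- stats::runif(n) < cfg$ld_rho
        hap[, j] <- ifelse(copy, hap[, j - 1L], fresh)
      } else {
        hap[, j] <- fresh
      }
    }
    dos <- dos + hap
  }

  g <- genotype_matrix(dos, sprintf("snp%05d", seq_len(m)),
                       paste0("chr", chrom_id), pos,
                       individual_ids = sprintf("ind%04d", seq_len(n)))
  attr(g, "population") <- pop
  g
}

#' Simulate a phenotype with specified heritability
#'
#' `y = g + e` with `g ~ N(0, h2 K)` (drawn through the eigendecomposition
#' of K, eigenvalues clipped at 0) and `e ~ N(0, (1 - h2) I)`.  The
#' heritability is the population parameter; the sample variance is not
#' renormalized.
#'
#' @param k a [kinship_matrix()].
#' @param h2 heritability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return A [phenotype_vector()].
#' @export
simulate_phenotype <- function(k, h2, seed = NULL) {
  mt_assert(inherits(k, "kinship_matrix"), "not a kinship_matrix")
  mt_assert(is.numeric(h2) && length(h2) == 1 && h2 >= 0 && h2 <= 1,
            "h2 must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(k$values)
  y <- stats::rnorm(n, sd = sqrt(1 - h2))
  if (h2 > 0) {
    ek <- eigen(k$values, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    y <- y + drop(ek$vectors %*% (sqrt(h2 * lam) * stats::rnorm(n)))
  }
  phenotype_vector(y, k$individual_ids)
}
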