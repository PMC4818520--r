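#' Construct a genotype matrix
#'
#' Container for an n-individual by m-marker dosage matrix plus marker
#' metadata.  Markers are sorted by (chromosome, position) on construction;
#' chromosome order follows first appearance, positions are 1-based
#' base-pair coordinates sorted ascending within each chromosome, as the
#' sliding-window machinery assumes genomic order.
#'
#' @param dosages numeric n x m matrix; raw allele counts in \{0, 1, 2\}
#'   (possibly with `NA`) or standardized real values.
#' @param marker_ids,chromosomes,positions length-m marker metadata.
#' @param individual_ids length-n identifiers (default `ind1..indn`).
#' @param standardized logical flag; if `TRUE` every column must have mean 0
#'   and variance 1 (denominator n) to 1e-8 and no missing entries.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `markers` (data frame: id, chrom, pos), `individual_ids`,
#'   `standardized`.
#' @export
genotype_matrix <- function(dosages, marker_ids, chromosomes, positions,
                            individual_ids = NULL, standardized = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  mt_assert(n >= 2, "need at least 2 individuals")
  mt_assert(m >= 1, "need at least 1 marker")
  mt_assert(length(marker_ids) == m && length(chromosomes) == m &&
              length(positions) == m, "marker metadata length mismatch")
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(marker_ids)) {
    mt_stop(sprintf("duplicate marker id(s): %s",
                    paste(unique(marker_ids[duplicated(marker_ids)]),
                          collapse = ", ")))
  }
  individual_ids <- individual_ids %||% paste0("ind", seq_len(n))
  mt_assert(length(individual_ids) == n, "individual_ids length mismatch")

  ord <- order(chrom_factor(chromosomes), positions)
  dosages <- dosages[, ord, drop = FALSE]
  markers <- data.frame(id = marker_ids[ord],
                        chrom = as.character(chromosomes)[ord],
                        pos = as.integer(positions)[ord],
                        stringsAsFactors = FALSE)
  colnames(dosages) <- markers$id
  rownames(dosages) <- individual_ids

  g <- structure(list(dosages = dosages, markers = markers,
                      individual_ids = as.character(individual_ids),
                      standardized = isTRUE(standardized)),
                 class = "genotype_matrix")
  if (g$standardized) {
    mt_assert(!anyNA(dosages), "standardized genotypes cannot contain NA")
    mu <- colMeans(dosages)
    v <- colMeans(sweep(dosages, 2L, mu, "-")^2)
    mt_assert(max(abs(mu)) < 1e-8 && max(abs(v - 1)) < 1e-8,
              "columns flagged standardized are not mean 0 / variance 1")
  }
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%s), %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (x$standardized) "standardized" else "raw dosages",
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Construct a phenotype vector
#'
#' @param values numeric vector of quantitative phenotype values.
#' @param individual_ids identifiers aligned to the genotype matrix rows.
#' @return Object of class `phenotype_vector`.
#' @export
phenotype_vector <- function(values, individual_ids = NULL) {
  values <- as.numeric(values)
  mt_assert(all(is.finite(values)), "phenotype values must be finite")
  mt_assert(length(values) >= 2, "need at least 2 phenotype values")
  structure(list(values = values,
                 individual_ids = as.character(
                   individual_ids %||% paste0("ind", seq_along(values)))),
            class = "phenotype_vector")
}

as_phenotype_values <- function(y) {
  if (inherits(y, "phenotype_vector")) y$values else as.numeric(y)
}

#' Read genotypes from disk
#'
#' Two dialects are supported.  The `matrix` format (EMMA/pylmm style) has
#' one row per marker: chromosome, marker id, position, reference-allele
#' placeholder, then one dosage per individual; missing dosages are coded
#' `NA` or `-9`.  The `plink-bed` format reads a PLINK `.bed`/`.bim`/`.fam`
#' triple (SNP-major layout only); `path` is the `.bed` file or the common
#' prefix.
#'
#' @param path file path.
#' @param format `"matrix"` or `"plink-bed"`.
#' @return A raw (unstandardized) [genotype_matrix()] with markers sorted by
#'   (chromosome, position).
#' @export
read_genotypes <- function(path, format = c("matrix", "plink-bed")) {
  format <- match.arg(format)
  if (format == "matrix") read_genotypes_matrix(path) else read_plink_bed(path)
}

read_genotypes_matrix <- function(path) {
  mt_assert(file.exists(path), sprintf("file not found: %s", path),
            "mt_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  mt_assert(length(lines) >= 1, "empty genotype file", "mt_io_error")
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (length(unique(nf)) != 1L || nf[1] < 5L) {
    bad <- which(nf != nf[1] | nf < 5L)[1]
    mt_stop(sprintf("malformed genotype line %d: expected %d fields, got %d",
                    bad, max(nf[1], 5L), nf[bad]), "mt_io_error")
  }
  m <- length(toks)
  n <- nf[1] - 4L
  mt_assert(n >= 2, "need at least 2 individuals")
  chrom <- vapply(toks, `[`, "", 1L)
  ids <- vapply(toks, `[`, "", 2L)
  pos <- suppressWarnings(as.integer(vapply(toks, `[`, "", 3L)))
  if (anyNA(pos)) {
    mt_stop(sprintf("malformed genotype line %d: non-integer position",
                    which(is.na(pos))[1]), "mt_io_error")
  }
  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    v <- toks[[j]][-(1:4)]
    v[v %in% c("NA", "-9", "-9.0")] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      mt_stop(sprintf("malformed genotype line %d: non-numeric dosage '%s'",
                      j, v[which(is.na(num) & !is.na(v))[1]]), "mt_io_error")
    }
    dos[, j] <- num
  }
  genotype_matrix(dos, ids, chrom, pos)
}

#' Write genotypes in the matrix text format
#'
#' Inverse of [read_genotypes()] for the `matrix` dialect; round-trips
#' dosages and metadata exactly.
#'
#' @param g a raw [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(g, path) {
  mt_assert(inherits(g, "genotype_matrix"), "not a genotype_matrix")
  d <- t(g$dosages)  # one row per marker
  rows <- vapply(seq_len(nrow(d)), function(j) {
    v <- format(d[j, ], trim = TRUE)
    v[is.na(d[j, ])] <- "NA"
    paste(c(g$markers$chrom[j], g$markers$id[j], g$markers$pos[j], "A",
            v), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

# PLINK .bed reader: magic 0x6c 0x1b, third byte 0x01 = SNP-major.
# 2-bit codes per individual: 00 hom A1 (dosage 2), 01 missing,
# 10 het (1), 11 hom A2 (0).  Dosage counts A1 alleles.
read_plink_bed <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    mt_assert(file.exists(f), sprintf("file not found: %s", f), "mt_io_error")
  }
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  mt_assert(ncol(bim_df) >= 6, "malformed .bim file", "mt_io_error")
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  mt_assert(length(raw) >= 3 && raw[1] == as.raw(0x6c) && raw[2] == as.raw(0x1b),
            "not a PLINK .bed file (bad magic number)", "mt_io_error")
  mt_assert(raw[3] == as.raw(0x01),
            "only SNP-major .bed layout is supported", "mt_io_error")
  bpm <- ceiling(n / 4)  # bytes per marker
  mt_assert(length(raw) == 3 + bpm * m,
            ".bed size inconsistent with .bim/.fam", "mt_io_error")
  body <- raw[-(1:3)]
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)  # col per byte
  # per byte, individuals fill bit pairs from the low end
  pairs <- bits[seq(1, 8, by = 2), , drop = FALSE] +
    2L * bits[seq(2, 8, by = 2), , drop = FALSE]
  codes <- matrix(as.vector(pairs), nrow = 4 * bpm)[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  genotype_matrix(dos, bim_df[[2]], bim_df[[1]], bim_df[[4]],
                  individual_ids = paste(fam_df[[1]], fam_df[[2]], sep = "_"))
}

#' Read a phenotype file
#'
#' Accepts either one value per line, or a two-column (id, value) TSV.
#'
#' @param path file path.
#' @return A [phenotype_vector()].
#' @export
read_phenotype <- function(path) {
  mt_assert(file.exists(path), sprintf("file not found: %s", path),
            "mt_io_error")
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    phenotype_vector(df[[1]])
  } else {
    phenotype_vector(df[[2]], individual_ids = df[[1]])
  }
}

#' Filter markers on minor allele frequency and missingness
#'
#' Keeps markers with MAF >= `maf_min` (computed on non-missing dosages as
#' `min(f, 1 - f)` with `f = mean(dosage)/2`) and missing fraction <=
#' `missing_max`.  Defaults follow the standard GWAS quality-control rule:
#' drop markers below 5 % MAF or above 10 % missingness.
#'
#' @param g raw [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param missing_max maximum missing fraction in `[0, 1]`.
#' @return Filtered [genotype_matrix()]; marker order preserved.
#' @export
filter_markers <- function(g, maf_min = 0.05, missing_max = 0.10) {
  mt_assert(inherits(g, "genotype_matrix"), "not a genotype_matrix")
  mt_assert(!g$standardized, "filter_markers expects raw dosages")
  mt_assert(maf_min >= 0 && maf_min <= 0.5, "maf_min must be in [0, 0.5]")
  mt_assert(missing_max >= 0 && missing_max <= 1,
            "missing_max must be in [0, 1]")
  d <- g$dosages
  miss <- colMeans(is.na(d))
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- which(maf >= maf_min & miss <= missing_max & !is.na(maf))
  if (!length(keep)) mt_stop("empty panel: all markers removed by filtering")
  genotype_matrix(d[, keep, drop = FALSE], g$markers$id[keep],
                  g$markers$chrom[keep], g$markers$pos[keep],
                  g$individual_ids)
}

#' Standardize genotype columns
#'
#' Missing entries are replaced by the column mean, then each column is
#' centered to mean 0 and scaled to variance 1 with denominator n
#' (population variance).  With this convention the Pearson correlation of
#' two standardized columns is their inner product divided by n.
#' Idempotent to numerical tolerance.
#'
#' @param g raw or standardized [genotype_matrix()]; every marker must be
#'   polymorphic among non-missing entries.
#' @return Standardized [genotype_matrix()].
#' @export
standardize <- function(g) {
  mt_assert(inherits(g, "genotype_matrix"), "not a genotype_matrix")
  d <- g$dosages
  if (anyNA(d)) {
    cm <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- cm[idx[, 2]]
  }
  cm <- colMeans(d)
  d <- sweep(d, 2L, cm, "-")
  v <- colMeans(d^2)
  bad <- which(v < 1e-12)
  if (length(bad)) {
    mt_stop(sprintf("zero-variance marker(s): %s (filter before standardizing)",
                    paste(g$markers$id[bad], collapse = ", ")),
            "mt_numerical_error")
  }
  d <- sweep(d, 2L, sqrt(v), "/")
  genotype_matrix(d, g$markers$id, g$markers$chrom, g$markers$pos,
                  g$individual_ids, standardized = TRUE)
}
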