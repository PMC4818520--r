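test_that("fixed-V bootstrap on independent markers matches Sidak", {
  # independent markers, identity kinship: min-p quantile has a closed form
  set.seed(5)
  m <- 80
  n <- 200
  x <- matrix(stats::rnorm(n * m), n, m)
  g <- standardize(genotype_matrix(x, paste0("s", seq_len(m)),
                                   rep("chr1", m), seq_len(m)))
  k <- kinship_matrix(diag(n))
  rb <- parametric_bootstrap(g, k, variance_components(0, 1),
                             n_reps = 2e4, seed = 6)
  tr <- per_marker_threshold(rb$min_p_dist, 0.05)
  # markers are near- but not exactly orthogonal; Sidak within a few se
  expect_lt(abs(tr$per_marker_threshold - sidak(0.05, m)), 4 * tr$mc_se)
})

test_that("fixed-V bootstrap agrees with the MVN sampler on a shared panel", {
  p <- make_panel(n = 100, m = 300, chromosomes = 2, seed = 43)
  vc <- variance_components(0.5, 0.5)
  tg <- transform_genotypes(p$std, build_covariance_model(p$kinship, vc))
  band <- windowed_correlation(tg, 60)
  t_mvn <- per_marker_threshold(
    sample_null_statistics(band, sampler_config(window = 60,
                                                n_samples = 2e4, seed = 44)),
    0.05)
  t_boot <- per_marker_threshold(
    parametric_bootstrap(p$std, p$kinship, vc, n_reps = 1e4,
                         seed = 45)$min_p_dist, 0.05)
  expect_lt(abs(t_mvn$per_marker_threshold - t_boot$per_marker_threshold),
            3 * sqrt(t_mvn$mc_se^2 + t_boot$mc_se^2) +
              0.1 * t_boot$per_marker_threshold)
})

test_that("full bootstrap (per-replicate refit) agrees with fixed-V", {
  p <- make_panel(n = 100, m = 60, seed = 47)
  vc <- variance_components(0.5, 0.5)
  rb_full <- suppressWarnings(
    parametric_bootstrap(p$std, p$kinship, vc, n_reps = 1000, seed = 48,
                         mode = "full"))
  rb_fix <- parametric_bootstrap(p$std, p$kinship, vc, n_reps = 10000,
                                 seed = 49)
  t_full <- per_marker_threshold(rb_full$min_p_dist, 0.05)
  t_fix <- per_marker_threshold(rb_fix$min_p_dist, 0.05)
  expect_lt(abs(t_full$per_marker_threshold - t_fix$per_marker_threshold),
            3 * sqrt(t_full$mc_se^2 + t_fix$mc_se^2))
  # cost refusal
  expect_error(parametric_bootstrap(p$std, p$kinship, vc, n_reps = 1e6,
                                    mode = "full", cost_budget = 1e9),
               "budget")
})

test_that("bootstrap p-values are calibrated under the generating model", {
  p <- make_panel(n = 100, m = 80, fst = 0.3, seed = 53)
  vc <- variance_components(0.7, 0.3)
  rb <- parametric_bootstrap(p$std, p$kinship, vc, n_reps = 300, seed = 54,
                             keep_pooled = TRUE)
  frac <- mean(rb$pooled_p < 0.05)
  n_tot <- length(rb$pooled_p)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("permutation is calibrated without structure but miscalibrated under it", {
  # no structure: identity kinship, independent phenotype
  set.seed(55)
  n <- 100
  m <- 60
  x <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  g <- standardize(genotype_matrix(x, paste0("s", seq_len(m)),
                                   rep("chr1", m), seq_len(m)))
  k_id <- kinship_matrix(diag(n))
  y <- stats::rnorm(n)
  pt <- suppressWarnings(permutation_test(g, k_id, y, n_perm = 150,
                                          seed = 56))
  frac <- mean(pt$pooled_p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(pt$pooled_p)))

  # strain-like structure with the model fitted on the observed phenotype:
  # permutation p-values depart from uniformity (here: conservative,
  # because structure-aligned markers are down-weighted under the fitted V)
  set.seed(57)
  nstrain <- 25
  reps <- 4
  xs <- matrix(stats::rbinom(nstrain * m, 2, 0.4), nstrain, m)
  xs <- xs[rep(seq_len(nstrain), each = reps), ]
  gs <- standardize(genotype_matrix(
    xs + matrix(stats::rbinom(100 * m, 1, 0.02), 100, m),
    paste0("s", seq_len(m)), rep("chr1", m), seq_len(m)))
  ks <- compute_kinship(gs)
  ys <- simulate_phenotype(ks, 0.7, seed = 58)
  pts <- suppressWarnings(permutation_test(gs, ks, ys, n_perm = 150,
                                           seed = 59, refit_vc = FALSE))
  fracs <- mean(pts$pooled_p < 0.05)
  expect_gt(abs(fracs - 0.05),
            3 * sqrt(0.05 * 0.95 / length(pts$pooled_p)))
  expect_error(permutation_test(g, k_id, y, n_perm = 50), "100")
})

test_that("qq_report computes -log10 plotting positions", {
  qq <- qq_report(c(0.5, 0.1, 1))
  expect_equal(qq$expected, -log10((1:3 - 0.5) / 3))
  expect_equal(qq$observed, -log10(c(0.1, 0.5, 1)))
  expect_equal(qq_report(rep(1, 5))$observed, rep(0, 5))
  expect_error(qq_report(c(0.5, 0)), "0, 1")
  # uniform grid lies on the diagonal
  qq2 <- qq_report((1:1000 - 0.5) / 1000)
  expect_lt(max(abs(qq2$expected - qq2$observed)), 1e-12)
})
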