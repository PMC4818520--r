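test_that("single marker: min-p is uniform on (0, 1)", {
  b <- indep_band(1, 1)
  mp <- sample_null_statistics(b, sampler_config(window = 1,
                                                 n_samples = 2e4, seed = 1))
  expect_gt(stats::ks.test(mp$min_p, "punif")$p.value, 0.01)
})

test_that("perfectly correlated markers act as a single test", {
  m <- 50
  band <- matrix(1, m, 10)
  band[1, ] <- 0
  for (d in 1:10) band[seq_len(min(d, m)), d] <- 0
  bc <- indep_band(m, 10)
  bc$band <- band
  mp <- sample_null_statistics(bc, sampler_config(window = 10,
                                                  n_samples = 2e4, seed = 2))
  # effective one test: min-p remains uniform
  expect_gt(stats::ks.test(mp$min_p, "punif")$p.value, 0.01)
})

test_that("independent markers reproduce the Sidak quantile", {
  m <- 100
  s <- 5e4
  mp <- sample_null_statistics(indep_band(m, 10),
                               sampler_config(window = 10, n_samples = s,
                                              seed = 3))
  u <- per_marker_threshold(mp, 0.05)
  expected <- sidak(0.05, m)
  expect_lt(abs(u$per_marker_threshold - expected), 2 * u$mc_se)
  # and for the dense sampler
  mp2 <- sample_exact_mvn(diag(10), sampler_config(n_samples = s, seed = 4))
  u2 <- per_marker_threshold(mp2, 0.05)
  expect_lt(abs(u2$per_marker_threshold - sidak(0.05, 10)), 2 * u2$mc_se)
  # all-ones covariance: one effective test
  mp3 <- sample_exact_mvn(matrix(1, 20, 20),
                          sampler_config(n_samples = 2e4, seed = 5))
  expect_gt(stats::ks.test(mp3$min_p, "punif")$p.value, 0.01)
})

test_that("sampler is deterministic given a seed and marginals are N(0,1)", {
  b <- ar1_band(50, 10, 0.6)
  cfg <- sampler_config(window = 10, n_samples = 5000, seed = 99)
  mp1 <- sample_null_statistics(b, cfg)
  mp2 <- sample_null_statistics(b, cfg)
  expect_identical(mp1$min_p, mp2$min_p)

  # pooled marginals: m = 1 chain draws are exactly the marginal draws
  b1 <- indep_band(1, 1)
  mp <- sample_null_statistics(b1, sampler_config(window = 1,
                                                  n_samples = 2e4, seed = 6))
  z <- stats::qnorm(mp$min_p / 2)  # reconstruct |S| as -z
  expect_gt(stats::ks.test(abs(z), function(q) {
    2 * stats::pnorm(q) - 1
  })$p.value, 0.01)
})

test_that("sliding window matches the dense Cholesky oracle", {
  # exactly banded AR(1) truth at scale
  b <- ar1_band(400, 60, 0.5)
  s <- 2e4
  mp1 <- sample_null_statistics(b, sampler_config(window = 60,
                                                  n_samples = s, seed = 7))
  mp2 <- sample_exact_mvn(b, sampler_config(n_samples = s, seed = 8))
  expect_gt(stats::ks.test(mp1$min_p, mp2$min_p)$p.value, 0.01)
  t1 <- per_marker_threshold(mp1, 0.05)
  t2 <- per_marker_threshold(mp2, 0.05)
  expect_lt(abs(t1$per_marker_threshold - t2$per_marker_threshold),
            2 * sqrt(t1$mc_se^2 + t2$mc_se^2))

  # empirical correlation band from a real panel, full window (exact Gram)
  p <- make_panel(n = 60, m = 120, chromosomes = 1, seed = 9)
  vc <- variance_components(0.5, 0.5)
  tg <- transform_genotypes(p$std, build_covariance_model(p$kinship, vc))
  bc <- windowed_correlation(tg, 119, noise_floor = 0)
  mp3 <- sample_null_statistics(bc, sampler_config(window = 119,
                                                   n_samples = 1e4, seed = 10))
  mp4 <- sample_exact_mvn(bc, sampler_config(n_samples = 1e4, seed = 11))
  expect_gt(stats::ks.test(mp3$min_p, mp4$min_p)$p.value, 0.01)
})

test_that("window consistency: short and long windows agree when LD is short-range", {
  b <- ar1_band(300, 100, 0.4)  # correlation range ~ a few markers
  s <- 2e4
  t_short <- per_marker_threshold(
    sample_null_statistics(b, sampler_config(window = 10, n_samples = s,
                                             seed = 12)), 0.05)
  t_long <- per_marker_threshold(
    sample_null_statistics(b, sampler_config(window = 100, n_samples = s,
                                             seed = 13)), 0.05)
  expect_lt(abs(t_short$per_marker_threshold - t_long$per_marker_threshold),
            2 * sqrt(t_short$mc_se^2 + t_long$mc_se^2))
})

test_that("chromosome boundaries reset the conditioning window", {
  m <- 60
  band <- matrix(0.9, m, 5)
  bc <- indep_band(m, 5)
  bc$band <- band
  bc$chromosomes <- rep(c("chr1", "chr2", "chr3"), each = 20)
  # mask entries that windowed_correlation would have zeroed
  for (d in 1:5) {
    i <- (d + 1):m
    bc$band[i, d][bc$chromosomes[i] != bc$chromosomes[i - d]] <- 0
    bc$band[seq_len(min(d, m)), d] <- 0
  }
  mp <- sample_null_statistics(bc, sampler_config(window = 5,
                                                  n_samples = 2e4, seed = 14))
  # three chromosomes of highly correlated markers: between Sidak for 3
  # and Sidak for 60 effective tests
  u <- per_marker_threshold(mp, 0.05)$per_marker_threshold
  expect_gt(u, sidak(0.05, 60))
  expect_lt(u, sidak(0.05, 2))
})

test_that("invalid configurations are rejected", {
  expect_error(sampler_config(window = 0), "window")
  expect_error(sampler_config(n_samples = 0), "n_samples")
  expect_error(sample_exact_mvn(diag(5001), sampler_config(n_samples = 10)),
               "5000")
})
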