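# equal-count binning, age matching, delta frequency and the test battery

mk_sites <- function(ages, freqs = runif(length(ages))) {
  tibble::tibble(variant_id = sprintf("s%04d", seq_along(ages)),
                 age = ages, derived_freq = freqs)
}

test_that("equal-count binning splits sorted ages with the remainder rule", {
  b10 <- assign_equal_count_age_bins(mk_sites(1:10), n_bins = 5)
  expect_equal(b10$bins$n, rep(2L, 5))
  b11 <- assign_equal_count_age_bins(mk_sites(1:11), n_bins = 5)
  expect_equal(b11$bins$n, c(3L, 2L, 2L, 2L, 2L))
  # bins ordered youngest -> oldest
  expect_true(all(diff(b11$bins$age_min) > 0))
  expect_error(assign_equal_count_age_bins(mk_sites(1:3), n_bins = 5), "at least")
  expect_error(assign_equal_count_age_bins(mk_sites(c(1, NA, 3)), n_bins = 2), "NA")
})

test_that("tied ages across a boundary follow the stable sorted partition", {
  ages <- c(5, 1, 5, 5, 2, 5, 5, 5)  # six ties spanning bin boundaries
  s <- mk_sites(ages)
  b <- assign_equal_count_age_bins(s, n_bins = 4)
  # oracle: stable partition of the (age, variant_id)-sorted sequence
  ord <- order(s$age, s$variant_id)
  oracle_bins <- rep(1:4, each = 2)[order(ord)]
  expect_equal(b$assignment$bin,
               oracle_bins[match(b$assignment$variant_id, s$variant_id)])
  expect_equal(b$bins$n, rep(2L, 4))
})

test_that("age matching reproduces focal bin counts and age multiset", {
  set.seed(1)
  focal <- mk_sites(sort(rgamma(50, 2, 0.01)))
  binning <- assign_equal_count_age_bins(focal, n_bins = 5)

  # neutral pool = exact copy of focal ages -> matched multiset equals focal's
  neutral <- mk_sites(focal$age)
  m <- match_downsample_neutral(neutral, binning, seed = 3)
  expect_equal(sort(m$age), sort(focal$age))
  expect_equal(as.vector(table(m$bin)), binning$bins$n)

  # larger pool: counts always match, ages stay inside bin ranges
  pool <- mk_sites(rgamma(5000, 2, 0.01))
  m2 <- match_downsample_neutral(pool, binning, seed = 4)
  expect_equal(as.vector(table(m2$bin)), binning$bins$n)
  for (b in 1:5) {
    expect_true(all(m2$age[m2$bin == b] >= binning$bins$age_min[b] &
                      m2$age[m2$bin == b] <= binning$bins$age_max[b]))
  }
  expect_error(match_downsample_neutral(mk_sites(1:10), binning), "smaller")
})

test_that("age matching achieves a small KS distance on large pools", {
  set.seed(2)
  focal <- mk_sites(rgamma(2000, 2, 0.005))
  binning <- assign_equal_count_age_bins(focal, n_bins = 5)
  pool <- mk_sites(rgamma(30000, 2, 0.005))
  m <- match_downsample_neutral(pool, binning, seed = 5)
  ks <- suppressWarnings(ks.test(m$age, focal$age)$statistic)
  expect_lt(ks, 0.05)
})

test_that("delta frequency is the difference of arithmetic means", {
  expect_equal(delta_frequency(rep(0.10, 4), rep(0.30, 7)), -0.20)
  expect_equal(delta_frequency(c(0.2, 0.4), c(0.2, 0.4)), 0)
  set.seed(6)
  a <- runif(100); b <- runif(50)
  expect_equal(delta_frequency(a, b), sum(a) / 100 - sum(b) / 50)
  expect_error(delta_frequency(numeric(0), 0.5), "non-empty")
})

test_that("resampled deltas are zero when the pool copies the focal set exactly", {
  set.seed(7)
  focal <- mk_sites(sort(rgamma(100, 2, 0.01)))
  neutral <- focal
  res <- resample_delta(focal, neutral, n_bins = 5, reps = 10, seed = 1)
  expect_true(all(res$deltas$delta == 0))
  expect_equal(res$reps, 10)
})

test_that("resampling is deterministic under a fixed seed and defaults to 100 reps", {
  set.seed(8)
  focal <- mk_sites(rgamma(100, 2, 0.01))
  pool <- mk_sites(rgamma(1000, 2, 0.01))
  r1 <- resample_delta(focal, pool, seed = 11)
  r2 <- resample_delta(focal, pool, seed = 11)
  expect_identical(r1$deltas, r2$deltas)
  expect_equal(r1$reps, 100)
  expect_equal(nrow(r1$deltas), 500)
  expect_true(all(r1$deltas$delta >= -1 & r1$deltas$delta <= 1))
})

test_that("frequency matching reproduces the target decile histogram", {
  set.seed(9)
  target <- rbeta(400, 0.5, 2)
  pool <- mk_sites(rgamma(5000, 2, 0.01), freqs = runif(5000))
  out <- frequency_match_resample(pool, target, seed = 2)
  expect_equal(nrow(out), length(target))
  brk <- seq(0, 1, 0.1)
  h_t <- table(cut(target, brk, include.lowest = TRUE))
  h_o <- table(cut(out$derived_freq, brk, include.lowest = TRUE))
  expect_true(all(abs(h_t - h_o) <= 1))
  # output is a genuine subsample of the pool
  expect_true(all(out$variant_id %in% pool$variant_id))
  expect_false(any(duplicated(out$variant_id)))
})

test_that("the frequency-match control mode off leaves the pipeline unchanged", {
  pair <- toy_site_pair(n_focal = 200, n_neutral = 2000, seed = 10)
  direct <- resample_delta(pair$focal, pair$neutral, n_bins = 5, reps = 20,
                           seed = 3)
  wrapped <- age_adjusted_sfs(pair$focal, pair$neutral, n_bins = 5, reps = 20,
                              seed = 3, min_bin_count = NULL)
  expect_identical(direct$deltas, wrapped$deltas)
})

fake_result <- function(delta_matrix) {
  # rows = replicates, cols = bins
  nb <- ncol(delta_matrix)
  reps <- nrow(delta_matrix)
  structure(list(
    deltas = tibble::tibble(
      replicate = rep(seq_len(reps), each = nb),
      bin = rep(seq_len(nb), times = reps),
      delta = as.vector(t(delta_matrix))),
    binning = list(n_bins = nb,
                   bins = tibble::tibble(bin = seq_len(nb), n = 100,
                                         age_min = seq_len(nb),
                                         age_max = seq_len(nb) + 1)),
    reps = reps, seed = 1, n_focal = 100, n_neutral = 1000),
    class = "delta_frequency_result")
}

test_that("the below-zero battery applies one-sided Wilcoxon with Bonferroni", {
  # all estimates at -0.1 in every bin: significant everywhere
  res <- fake_result(matrix(-0.1, nrow = 100, ncol = 5))
  out <- test_delta_below_zero(res, alpha = 0.01)
  expect_true(all(out$significant))
  # Bonferroni multiplies by the number of bins (capped at 1)
  expect_equal(out$p_adjusted, pmin(1, out$p_value * 5))

  # all-zero estimates: p = 1, no signal, not an error
  res0 <- fake_result(matrix(0, nrow = 50, ncol = 3))
  out0 <- test_delta_below_zero(res0)
  expect_true(all(out0$p_value == 1))
  expect_false(any(out0$significant))

  # symmetric noise around zero is non-significant for this seed battery
  set.seed(12)
  n_sig <- vapply(1:20, function(i) {
    m <- matrix(rnorm(100 * 3, 0, 0.05), 100, 3)
    m <- m - mean(m)  # symmetric around 0
    sum(test_delta_below_zero(fake_result(m))$significant)
  }, numeric(1))
  expect_true(mean(n_sig == 0) >= 0.95)
})

test_that("oldest-vs-others flags only a uniformly lower oldest bin", {
  m <- cbind(matrix(-0.05, 100, 4), rep(-0.3, 100))
  m <- m + rnorm(length(m), 0, 0.01)
  out <- test_oldest_vs_others(fake_result(m), alpha = 0.01)
  expect_equal(nrow(out), 4)
  expect_true(all(out$significant))
  expect_true(pattern_reproduced(out))

  # oldest equal to others: not flagged
  m2 <- matrix(rnorm(100 * 5, -0.1, 0.02), 100, 5)
  out2 <- test_oldest_vs_others(fake_result(m2))
  expect_false(pattern_reproduced(out2))

  # two bins: a single uncorrected comparison
  m3 <- cbind(rnorm(50, 0, 0.01), rnorm(50, -0.2, 0.01))
  out3 <- test_oldest_vs_others(fake_result(m3))
  expect_equal(nrow(out3), 1)
  expect_equal(out3$p_adjusted, out3$p_value)
})

test_that("label swap of identical datasets gives deltas symmetric about zero", {
  set.seed(13)
  a <- mk_sites(rgamma(300, 2, 0.01))
  b <- mk_sites(rgamma(300, 2, 0.01))
  r_ab <- suppressWarnings(resample_delta(a, b, n_bins = 3, reps = 50, seed = 5))
  r_ba <- suppressWarnings(resample_delta(b, a, n_bins = 3, reps = 50, seed = 5))
  pooled <- c(r_ab$deltas$delta, r_ba$deltas$delta)
  expect_lt(abs(mean(pooled)), 0.02)
})

test_that("comparison sets are capped per group at the configured maximum", {
  sites <- tibble::tibble(
    clade = rep(c("A", "B"), each = 200),
    effect = rep(c("non_synonymous", "high_effect"), 200),
    x = 1:400)
  out <- cap_group_size(sites, max_n = 50, seed = 1)
  tab <- dplyr::count(out, clade, effect)
  expect_true(all(tab$n == 50))
  small <- cap_group_size(sites, max_n = 5000, seed = 1)
  expect_equal(nrow(small), 400)
})
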