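spec_plain <- function(n = 30, ...) {
  synthetic_spec(n_bins = n, tad_boundaries = integer(0), tad_enrichment = 1,
                 loops = data.frame(), ...)
}

test_that("intensity surface follows the closed-form decay", {
  lam <- ground_truth_intensity(spec_plain())$values
  expect_equal(lam[1, 1], 1)
  expect_equal(lam[1, 2], 0.5)
  expect_equal(lam[3, 9], 1 / 7)
  d <- abs(row(lam) - col(lam))
  expect_equal(lam, (1 + d)^-1, ignore_attr = TRUE)
})

test_that("same-TAD pairs are enriched by exactly tad_enrichment", {
  spec <- synthetic_spec(n_bins = 40, tad_boundaries = c(20L),
                         tad_enrichment = 3, loops = data.frame())
  lam <- ground_truth_intensity(spec)$values
  # bins 4,9 same TAD; bins 17,22 straddle the boundary; same |i - j| = 5
  expect_equal(lam[5, 10] / lam[18, 23], 3)
})

test_that("a loop adds a Gaussian bump of the stated amplitude", {
  base <- spec_plain(n = 60)
  with_loop <- synthetic_spec(n_bins = 60, tad_boundaries = integer(0),
                              tad_enrichment = 1,
                              loops = data.frame(anchor_i = 10, anchor_j = 45,
                                                 amplitude = 2.5, width = 1))
  delta <- ground_truth_intensity(with_loop)$values -
    ground_truth_intensity(base)$values
  expect_equal(delta[11, 46], 2.5, tolerance = 1e-10)
  expect_equal(delta[46, 11], 2.5, tolerance = 1e-10)
  # bump decays within a few bins
  expect_lt(delta[11, 51], 2.5 * exp(-12))
})

test_that("expected intensity decays monotonically with distance", {
  lam <- ground_truth_intensity(
    synthetic_spec(n_bins = 50, loops = data.frame()))$values
  by_d <- vapply(0:49, function(k) {
    idx <- cbind(seq_len(50 - k), seq_len(50 - k) + k)
    mean(lam[idx])
  }, numeric(1))
  expect_true(all(diff(by_d) <= 1e-12))
})

test_that("count sampling is seeded, banded and calibrated to depth", {
  spec <- synthetic_spec(n_bins = 60, depth = 2e4)
  lam <- ground_truth_intensity(spec)
  a <- sample_counts(lam, spec$depth, max_dist = 2e5, seed = 11)
  b <- sample_counts(lam, spec$depth, max_dist = 2e5, seed = 11)
  expect_identical(a$values, b$values)
  expect_true(all(a$values == round(a$values)))
  expect_true(all(a$values >= 0))
  expect_identical(a$values, t(a$values))
  d <- abs(row(a$values) - col(a$values))
  expect_true(all(a$values[d > 20] == 0))

  # Poisson total: observed in-band totals stay within 4 sqrt(depth)
  tots <- vapply(1:20, function(s) {
    v <- sample_counts(lam, spec$depth, max_dist = 2e5, seed = s)$values
    sum(v[upper.tri(v, diag = TRUE)])
  }, numeric(1))
  expect_true(all(abs(tots - spec$depth) < 4 * sqrt(spec$depth)))
})

test_that("uniform intensity spreads depth evenly over band cells", {
  flat <- contact_matrix(matrix(1, 40, 40), is_normalized = TRUE)
  depth <- 1e5
  cnt <- sample_counts(flat, depth, max_dist = 10 * 10000, seed = 3)$values
  d <- abs(row(cnt) - col(cnt))
  cells <- cnt[upper.tri(cnt, diag = TRUE) & d <= 10]
  expect_equal(mean(cells), depth / length(cells), tolerance = 0.05)
})

test_that("doubling depth doubles expected totals", {
  spec <- synthetic_spec(n_bins = 50)
  lam <- ground_truth_intensity(spec)
  t1 <- mean(vapply(1:10, function(s)
    sum(sample_counts(lam, 1e4, 2e5, seed = s)$values), numeric(1)))
  t2 <- mean(vapply(1:10, function(s)
    sum(sample_counts(lam, 2e4, 2e5, seed = 100 + s)$values), numeric(1)))
  expect_equal(t2 / t1, 2, tolerance = 0.05)
})

test_that("make_pair thins the deep matrix by the requested fraction", {
  spec <- synthetic_spec(n_bins = 80, depth = 5e4, seed = 5)
  pair1 <- make_pair(spec, fraction = 1)
  expect_identical(pair1$low$values, pair1$high$values)

  pair <- make_pair(spec, fraction = 1 / 16)
  tot_high <- sum(pair$high$values)
  ratio <- sum(pair$low$values) / tot_high
  sigma <- sqrt((1 / 16) * (15 / 16) / tot_high)
  expect_lt(abs(ratio - 1 / 16), 3 * sigma)

  # reproducible end to end
  pair2 <- make_pair(spec, fraction = 1 / 16)
  expect_identical(pair2$high$values, pair$high$values)
  expect_identical(pair2$low$values, pair$low$values)
})

test_that("planted TAD structure is recoverable from sampled counts", {
  spec <- synthetic_spec(n_bins = 100, tad_boundaries = c(50L),
                         tad_enrichment = 3, loops = data.frame(),
                         depth = 2e5)
  high <- make_pair(spec, fraction = 1)$high$values
  # at fixed distance 10, within-TAD pairs should out-count cross-boundary pairs
  k <- 10
  idx <- cbind(seq_len(100 - k), seq_len(100 - k) + k)
  within <- idx[, 2] <= 50 | idx[, 1] >= 51
  expect_gt(mean(high[idx[within, ]]), mean(high[idx[!within, ]]))
})

test_that("spec validation rejects inconsistent structure", {
  expect_error(synthetic_spec(tad_boundaries = c(10L, 5L)), "increasing")
  expect_error(synthetic_spec(loops = data.frame(anchor_i = 5, anchor_j = 5,
                                                 amplitude = 1, width = 1)),
               "anchor")
  expect_error(synthetic_spec(depth = 0), "depth")
})
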