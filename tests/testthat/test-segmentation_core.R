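test_that("segment_cost matches its closed form on small windows", {
  cs <- series_from_matrix(matrix(c(2, 2, 2), 1))
  expect_equal(segment_cost(cs, 1, 3), 0)                 # pure category
  cs <- series_from_matrix(matrix(c(0, 1), 1))
  expect_equal(segment_cost(cs, 1, 2), 2 * log(1 / 2))
  cs <- series_from_matrix(rbind(c(0, 1), c(0, 3)))       # pooled plants
  expect_equal(segment_cost(cs, 1, 2), 2 * log(0.5) + 2 * log(0.25))
  expect_error(segment_cost(cs, 2, 1), "u <= v")
})

test_that("cost_matrix agrees with segment_cost on every window", {
  cs <- random_series(3, 8, seed = 11)
  cm <- cost_matrix(cs)
  for (u in 1:8) for (v in u:8)
    expect_equal(cm[u, v], segment_cost(cs, u, v))
})

test_that("dynamic programme finds pure phases and documented tie-breaks", {
  cs <- series_from_matrix(matrix(c(0, 0, 0, 3, 3, 3), 1))
  m <- optimal_segmentation(cs, 2)
  expect_equal(m$segmentation$change_points, 4L)
  expect_equal(m$log_likelihood, 0)
  expect_equal(unname(m$theta[1, "0"]), 1)
  expect_equal(unname(m$theta[2, "3"]), 1)
  # constant series: all segmentations tie; leftmost change points win
  cs0 <- series_from_matrix(matrix(1, 1, 7))
  for (J in 2:4) {
    m0 <- optimal_segmentation(cs0, J)
    expect_equal(m0$segmentation$change_points, 2:J)
    expect_equal(m0$log_likelihood, segment_cost(cs0, 1, 7))
  }
  expect_error(optimal_segmentation(cs0, 8), "J must")
})

test_that("segmentation counts match the closed form and explicit enumeration", {
  expect_equal(count_segmentations(28, 3), 351)
  expect_equal(count_segmentations(28, 4), 2925)
  expect_equal(count_segmentations(10, 1), 1)
  expect_equal(count_segmentations(10, 10), 1)
  expect_equal(count_segmentations(5, 7), 0)
  for (T in c(5, 9)) for (J in 1:4)
    expect_equal(nrow(enumerate_segmentations(T, J)),
                 count_segmentations(T, J))
})

test_that("log marginal likelihood respects its exact identities and bounds", {
  cs <- random_series(2, 9, seed = 3)
  T <- 9
  expect_equal(log_marginal(cs, 1), segment_cost(cs, 1, T))
  # saturated one-plant model: every singleton segment is pure
  cs1 <- random_series(1, 6, seed = 4)
  expect_equal(log_marginal(cs1, 6), 0)
  for (J in 1:4) {
    opt <- optimal_segmentation(cs, J)
    lm <- log_marginal(cs, J)
    expect_gte(lm, opt$log_likelihood - 1e-12)
    expect_lte(lm, opt$log_likelihood + log(count_segmentations(T, J)) + 1e-12)
  }
})

test_that("optimal log-likelihood is non-decreasing in J", {
  cs <- random_series(3, 10, seed = 9)
  ll <- vapply(1:6, function(J)
    optimal_segmentation(cs, J)$log_likelihood, numeric(1))
  expect_true(all(diff(ll) >= -1e-12))
})

test_that("segmentation entropy: degenerate cases and path agreement", {
  cs <- random_series(2, 8, seed = 6)
  expect_equal(segmentation_entropy(cs, 1), 0)             # one segmentation
  cs2 <- series_from_matrix(matrix(c(0, 0), 1))
  expect_equal(segmentation_entropy(cs2, 2), 0)            # T=2, J=2 unique
  for (J in 2:4) {
    hs <- segmentation_entropy(cs, J, method = "smoothing")
    he <- segmentation_entropy(cs, J, method = "enumeration")
    expect_equal(hs, he, tolerance = 1e-10)
    expect_gte(hs, 0)
    expect_lte(hs, log(count_segmentations(8, J)) + 1e-12)
  }
})

test_that("ICL reduces to its closed form at J = 1 and rewards real structure", {
  cs <- random_series(2, 10, seed = 8)
  C <- cs$n_categories
  expect_equal(icl(cs, 1), 2 * segment_cost(cs, 1, 10) - (C - 1) * log(10))
  # well-separated two-phase panel: two phases beat one (the parameter
  # penalty scales with the 6 categories, so two plants are needed for the
  # fit gain to dominate over 8 weeks)
  m2 <- matrix(rep(c(0, 3), each = 4), 2, 8, byrow = TRUE)
  cs2 <- series_from_matrix(m2)
  expect_gt(icl(cs2, 2), icl(cs2, 1))
  # the d override and the cumulative-size penalty hook are honoured
  expect_equal(icl(cs, 1, d = 0), 2 * log_marginal(cs, 1))
  expect_lt(icl(cs, 2, penalty = "logPT"), icl(cs, 2, penalty = "logT"))
})

test_that("model posteriors normalise and recover a well-separated design", {
  cs <- random_series(2, 10, seed = 12)
  expect_equal(unname(model_posteriors(cs, 1)), 1)
  p <- model_posteriors(cs, 5)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  # 3 well-separated phases, 30 plants: ICL posterior peaks at J = 3
  cfg <- synthetic_config(
    n_genotypes = c(three_phase = 1L), plants_per_genotype = 30L,
    phase_means = list(three_phase = c(1.2, 0.05, 2.5)), seed = 21L)
  cs3 <- encode_counts(sample_panel(cfg)$panels[[1]])
  expect_equal(unname(which.max(model_posteriors(cs3, 6))), 3)
})

test_that("posterior of the optimal segmentation behaves as a probability", {
  cs <- random_series(3, 9, seed = 14)
  m1 <- optimal_segmentation(cs, 1)
  expect_equal(segmentation_posterior(cs, m1), 1)
  for (J in 2:4) {
    m <- optimal_segmentation(cs, J)
    post <- segmentation_posterior(cs, m)
    expect_gt(post, 0)
    expect_lte(post, 1)
    expect_gte(post, 1 / count_segmentations(9, J) - 1e-12)
  }
  # pure-phase series: rivals carry strictly less weight
  csp <- series_from_matrix(matrix(c(0, 0, 0, 3, 3, 3), 1))
  mp <- optimal_segmentation(csp, 2)
  expect_equal(segmentation_posterior(csp, mp),
               oracle_full(csp, 2)$best_posterior, tolerance = 1e-10)
})

test_that("top-N lists are consistent, ordered and complete", {
  cs <- random_series(2, 8, seed = 16)
  top1 <- top_segmentations(cs, 3, 1)
  opt <- optimal_segmentation(cs, 3)
  expect_equal(top1$log_likelihood, opt$log_likelihood)
  expect_equal(as.integer(top1[1, c("cp1", "cp2")]),
               opt$segmentation$change_points)
  expect_equal(top1$posterior, segmentation_posterior(cs, opt),
               tolerance = 1e-10)
  full <- top_segmentations(cs, 3, count_segmentations(8, 3))
  expect_equal(sum(full$posterior), 1, tolerance = 1e-9)
  expect_true(all(diff(full$posterior) <= 1e-12))
})

test_that("posterior profiles are exact probability grids", {
  cs <- random_series(3, 9, seed = 18)
  p1 <- posterior_profiles(cs, 1)
  expect_equal(p1$occupancy[, 1], rep(1, 9))
  for (J in 2:4) {
    pr <- posterior_profiles(cs, J)
    expect_equal(rowSums(pr$occupancy), rep(1, 9), tolerance = 1e-9)
    expect_equal(unname(colSums(pr$entry)[2:J]), rep(1, J - 1),
                 tolerance = 1e-9)
  }
})

test_that("every engine output matches brute-force enumeration on random panels", {
  set.seed(2024)
  for (rep in 1:30) {
    P <- sample(1:3, 1)
    T <- sample(4:10, 1)
    J <- sample(1:min(4, T), 1)
    cs <- random_series(P, T, cap = sample(2:5, 1), seed = 3000 + rep)
    expect_oracle_agreement(cs, J)
  }
})

test_that("recursions stay finite in log-space on large panels", {
  cs <- random_series(300, 60, cap = 5, max_count = 8, seed = 99)
  expect_true(is.finite(log_marginal(cs, 4)))
  h <- segmentation_entropy(cs, 4)
  expect_true(is.finite(h) && h >= 0)
  expect_true(is.finite(icl(cs, 4)))
})

test_that("segment_series assembles a coherent report", {
  cfg <- synthetic_config(n_genotypes = c(four_phase = 1L), seed = 42L)
  cs <- encode_counts(sample_panel(cfg)$panels[[1]])
  rep <- segment_series(cs, Jmax = 5, top_n = 3, profiles = TRUE)
  expect_equal(sum(rep$model_posteriors), 1, tolerance = 1e-9)
  expect_equal(rep$icl_J, 4L)
  for (e in rep$per_J) {
    expect_equal(e$optimal_posterior,
                 exp(e$optimal$log_likelihood - e$log_marginal),
                 tolerance = 1e-12)
    expect_gte(e$entropy, 0)
    expect_equal(nrow(e$top), min(3, count_segmentations(28, e$J)))
    expect_equal(rowSums(e$profiles$occupancy), rep(1, 28), tolerance = 1e-9)
  }
})
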