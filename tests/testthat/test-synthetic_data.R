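test_that("the same seed reproduces the whole study byte-for-byte", {
  cfg <- synthetic_config(n_genotypes = c(three_phase = 1L, four_phase = 1L,
                                          seasonal = 1L),
                          plants_per_genotype = 5L, seed = 33L)
  a <- sample_study(cfg)
  b <- sample_study(cfg)
  expect_identical(a, b)
  # and a different seed does not
  cfg2 <- synthetic_config(n_genotypes = c(four_phase = 1L),
                           plants_per_genotype = 5L, seed = 34L)
  expect_false(identical(sample_panel(cfg2)$panels[[1]]$counts,
                         sample_panel(cfg)$panels[[2]]$counts))
})

test_that("phase distributions hit their prescribed means with the right shape", {
  for (m in c(0.10, 0.45, 0.92, 1.65)) {
    p <- flophase:::phase_pmf(m)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(sum(0:8 * p), m, tolerance = 1e-9)
    expect_equal(which.max(p) - 1L, if (m < 1) 0L else 1L)  # mode 0 or 1
  }
  expect_equal(flophase:::phase_pmf(0), c(1, rep(0, 8)))
})

test_that("a degenerate one-phase point-mass config yields an all-zero panel", {
  cfg <- synthetic_config(n_genotypes = c(three_phase = 1L),
                          plants_per_genotype = 4L,
                          change_weeks = list(three_phase = integer(0)),
                          phase_means = list(three_phase = 0), seed = 2L)
  pan <- sample_panel(cfg)$panels[[1]]
  expect_true(all(pan$counts == 0))
  expect_equal(dim(pan$counts), c(4L, 28L))
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(synthetic_config(n_genotypes = c(three_phase = 1L),
                                theta = list(three_phase = rbind(rep(0.5, 9)))),
               "probability")
  expect_error(synthetic_config(n_genotypes = c(four_phase = 1L),
                                change_weeks = list(four_phase = c(25L, 19L, 31L))),
               "increasing")
  expect_error(synthetic_config(n_genotypes = c(four_phase = 1L),
                                penetrance = 1.5), "penetrance")
})

test_that("empirical phase means match the generating model", {
  cfg <- synthetic_config(n_genotypes = c(four_phase = 1L), seed = 8L)
  pan <- sample_panel(cfg)$panels[[1]]
  # phase 4 spans weeks 31-43: 30 plants x 13 weeks = 390 draws at mean 1.65
  late <- pan$counts[, 16:28]
  se <- stats::sd(late) / sqrt(length(late))
  expect_lt(abs(mean(late) - 1.65), 3 * se)
})

test_that("marker states follow the pattern at full penetrance and flip below it", {
  cfg <- synthetic_config(n_genotypes = c(three_phase = 4L, four_phase = 4L),
                          plants_per_genotype = 2L, seed = 5L)
  s <- sample_panel(cfg)
  expect_equal(s$markers$state[grepl("^TP", s$markers$genotype)], rep("H", 4))
  expect_equal(s$markers$state[grepl("^FP", s$markers$genotype)], rep("A", 4))
  cfg0 <- synthetic_config(n_genotypes = c(three_phase = 4L, four_phase = 4L),
                           plants_per_genotype = 2L, penetrance = 0,
                           seed = 5L)
  s0 <- sample_panel(cfg0)
  expect_equal(s0$markers$state[grepl("^TP", s0$markers$genotype)], rep("A", 4))
  expect_equal(s0$markers$state[grepl("^FP", s0$markers$genotype)], rep("H", 4))
})

test_that("sampled panels round-trip through the CSV reader and encoder", {
  cfg <- synthetic_config(n_genotypes = c(four_phase = 2L),
                          plants_per_genotype = 6L, seed = 44L)
  panels <- sample_panel(cfg)$panels
  path <- tempfile(fileext = ".csv")
  write_panel(panels, path)
  back <- load_panel(path)
  for (g in names(panels)) {
    expect_equal(unname(back[[g]]$counts), unname(panels[[g]]$counts))
    expect_equal(encode_counts(back[[g]])$values,
                 pmin(panels[[g]]$counts, 5L), ignore_attr = TRUE)
  }
})

test_that("stolon emergence is budget-coupled against flowering", {
  cfg <- synthetic_config(n_genotypes = c(four_phase = 1L, seasonal = 1L),
                          seed = 19L)
  s <- sample_panel(cfg)
  st <- sample_stolons(cfg, s)
  # seasonal-habit plants runner much more than perpetual-flowering plants
  tot_sf <- rowSums(st$SF_01$counts)
  tot_pf <- rowSums(st$FP_01$counts)
  ht <- t.test(tot_sf, tot_pf, alternative = "greater")
  expect_lt(ht$p.value, 0.01)
  # pooled rank correlation between flowering and runnering rates is negative
  dates <- cfg$stolon_dates
  infl_rates <- lapply(names(s$panels), function(g) {
    idx <- match(dates, s$panels[[g]]$weeks)
    # weekly inflorescence rate at the stolon dates (mean over plants)
    colMeans(s$panels[[g]]$counts[, idx, drop = FALSE])
  })
  stol_rates <- lapply(names(s$panels), function(g)
    colMeans(st[[g]]$rates$rates))
  r <- rate_correlation(unlist(infl_rates), unlist(stol_rates))
  expect_lt(r$coefficient, 0)
  # zero budget silences stolon production entirely
  cfg0 <- synthetic_config(n_genotypes = c(seasonal = 1L),
                           plants_per_genotype = 4L,
                           stolon_budget = 0, seed = 3L)
  s0 <- sample_panel(cfg0)
  st0 <- sample_stolons(cfg0, s0)
  expect_true(all(st0$SF_01$counts == 0))
})

test_that("with no jitter the generator lies inside the fitted model family", {
  # the average optimal log-likelihood per observation approaches the
  # negative entropy of the (capped) generating distribution in each phase
  cfg <- synthetic_config(n_genotypes = c(three_phase = 1L),
                          plants_per_genotype = 400L, seed = 60L)
  s <- sample_panel(cfg)
  cs <- encode_counts(s$panels[[1]])
  opt <- optimal_segmentation(cs, 3)
  cap_entropy <- function(p) {
    pc <- c(p[1:5], sum(p[6:9]))
    pc <- pc[pc > 0]
    -sum(pc * log(pc))
  }
  lens <- c(4, 5, 19) / 28
  expected <- -sum(lens * apply(cfg$theta$three_phase, 1, cap_entropy))
  expect_equal(opt$log_likelihood / length(cs$values), expected,
               tolerance = 0.01)
})

test_that("season totals line up with the generating phase structure", {
  cfg <- synthetic_config(n_genotypes = c(three_phase = 2L, four_phase = 2L),
                          seed = 71L)
  st <- sample_study(cfg)
  et <- st$end_of_season
  expect_equal(nrow(et), 4 * 30)
  # inflorescence season totals are the panel row sums by construction
  expect_equal(et$n_inflorescences[et$genotype == "TP_01"],
               unname(rowSums(st$panels$TP_01$counts)))
  agg <- aggregate(n_inflorescences ~ genotype, et, mean)
  # expected totals: three-phase 4*0.45 + 5*0.10 + 19*0.92 = 19.78;
  # four-phase 3*0.45 + 6*0.10 + 6*0.92 + 13*1.65 = 28.92
  expect_equal(mean(agg$n_inflorescences[grepl("^TP", agg$genotype)]),
               19.78, tolerance = 0.15)
  expect_equal(mean(agg$n_inflorescences[grepl("^FP", agg$genotype)]),
               28.92, tolerance = 0.15)
})
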