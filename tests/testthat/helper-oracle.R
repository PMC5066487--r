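# Brute-force oracle for the segmentation engine: enumerates every
# segmentation explicitly and scores each segment from a plain table() of
# its values. Deliberately shares no code with the package's cumulative-count
# cost table or forward-backward recursions.

oracle_score <- function(values, C, cps) {
  T <- ncol(values)
  starts <- c(1L, cps)
  ends <- c(cps - 1L, T)
  s <- 0
  for (j in seq_along(starts)) {
    v <- values[, starts[j]:ends[j], drop = FALSE]
    n <- as.integer(table(factor(v, levels = 0:(C - 1))))
    n <- n[n > 0]
    s <- s + sum(n * log(n / sum(n)))
  }
  s
}

# All J-phase segmentations with scores, posterior, entropy, best (with
# lexicographic tie-break on change points), occupancy/entry grids.
oracle_full <- function(series, J) {
  values <- series$values
  C <- series$n_categories
  T <- ncol(values)
  if (J == 1) {
    segs <- matrix(integer(0), 1, 0)
    scores <- oracle_score(values, C, integer(0))
  } else {
    segs <- t(utils::combn(2:T, J - 1))
    scores <- vapply(seq_len(nrow(segs)), function(i)
      oracle_score(values, C, as.integer(segs[i, ])), numeric(1))
  }
  m <- max(scores)
  logM <- m + log(sum(exp(scores - m)))
  p <- exp(scores - logM)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  best <- which(scores >= m - 1e-12)
  if (length(best) > 1 && J > 1) {
    o <- do.call(order, as.data.frame(segs[best, , drop = FALSE]))
    best <- best[o[1]]
  } else {
    best <- best[1]
  }
  occ <- matrix(0, T, J)
  ent <- matrix(0, T, J)
  for (i in seq_len(nrow(segs))) {
    cps <- if (J > 1) as.integer(segs[i, ]) else integer(0)
    starts <- c(1L, cps)
    ends <- c(cps - 1L, T)
    for (j in seq_len(J)) {
      occ[starts[j]:ends[j], j] <- occ[starts[j]:ends[j], j] + p[i]
      ent[starts[j], j] <- ent[starts[j], j] + p[i]
    }
  }
  list(segs = segs, scores = scores, logM = logM, entropy = H,
       best_score = m,
       best_cps = if (J > 1) as.integer(segs[best, ]) else integer(0),
       best_posterior = p[best], posterior = p,
       occupancy = occ, entry = ent)
}

# Compare every engine output against the oracle for one (series, J).
expect_oracle_agreement <- function(series, J, tol = 1e-9, top_n = 5L) {
  orc <- oracle_full(series, J)
  cost <- flophase::cost_matrix(series)

  opt <- optimal_segmentation(series, J, cost = cost)
  expect_equal(opt$log_likelihood, orc$best_score, tolerance = tol)
  expect_equal(opt$segmentation$change_points, orc$best_cps)

  expect_equal(log_marginal(series, J, cost = cost), orc$logM,
               tolerance = tol)
  expect_equal(segmentation_entropy(series, J, cost = cost), orc$entropy,
               tolerance = tol)
  expect_equal(segmentation_posterior(series, opt, cost = cost),
               orc$best_posterior, tolerance = tol)

  prof <- posterior_profiles(series, J, cost = cost)
  expect_equal(prof$occupancy, orc$occupancy, tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(prof$entry, orc$entry, tolerance = tol, ignore_attr = TRUE)

  n <- min(top_n, nrow(orc$segs))
  top <- top_segmentations(series, J, n, cost = cost)
  expect_equal(top$log_likelihood,
               sort(orc$scores, decreasing = TRUE)[seq_len(n)],
               tolerance = tol)
  expect_equal(top$posterior,
               sort(orc$posterior, decreasing = TRUE)[seq_len(n)],
               tolerance = tol)
  invisible(TRUE)
}
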