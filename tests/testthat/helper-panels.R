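# Small fixture builders used across test files.

panel_from_matrix <- function(m, genotype = "g", weeks = NULL) {
  m <- as.matrix(m)
  if (is.null(weeks)) weeks <- seq_len(ncol(m))
  genotype_panel(genotype, m, weeks = weeks)
}

series_from_matrix <- function(m, cap = 5L, ...) {
  encode_counts(panel_from_matrix(m, ...), cap = cap)
}

# Random small panel for oracle comparisons: counts drawn on 0..max_count,
# then capped, so the grouping rule is exercised too.
random_series <- function(P, T, cap = 3L, max_count = 5L, seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(0:max_count, P * T, replace = TRUE), P, T)
  series_from_matrix(m, cap = cap)
}

write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
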