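#' Aligned weekly count panel for one genotype
#'
#' A `genotype_panel` holds the synchronous weekly organ-emergence counts for
#' all plants of one genotype: a P x T integer matrix whose rows are plants
#' and whose columns are consecutive calendar weeks. This is the multivariate
#' series that the multiple change-point model segments -- every plant is one
#' variable, every column one measurement date.
#'
#' @param genotype single genotype identifier.
#' @param counts P x T matrix of non-negative integer counts; rows may be
#'   named by plant.
#' @param weeks integer vector of T contiguous calendar-week labels
#'   (e.g. `16:43`).
#' @param plants character vector of P plant identifiers; defaults to the
#'   rownames of `counts` or `"p1".."pP"`.
#' @param organ organ being counted, `"inflorescence"` or `"stolon"`.
#'
#' @return An object of class `genotype_panel` with fields `genotype`,
#'   `plants`, `weeks`, `counts`, `organ`.
#' @examples
#' pan <- genotype_panel("G1", matrix(rpois(60, 1), 3, 20), weeks = 16:35)
#' dim(pan$counts)
#' @export
genotype_panel <- function(genotype, counts, weeks,
                           plants = NULL,
                           organ = c("inflorescence", "stolon")) {
  organ <- match.arg(organ)
  counts <- as.matrix(counts)
  if (is.null(plants)) {
    plants <- rownames(counts)
    if (is.null(plants)) plants <- paste0("p", seq_len(nrow(counts)))
  }
  weeks <- as.integer(weeks)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("panel needs at least one plant and one week")
  if (length(weeks) != ncol(counts))
    stop("length(weeks) must equal ncol(counts)")
  if (any(diff(weeks) != 1L))
    stop("weeks must be contiguous integers")
  if (length(plants) != nrow(counts))
    stop("length(plants) must equal nrow(counts)")
  if (anyNA(counts))
    stop("panel counts must not contain missing values")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("panel counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(plants, weeks)
  structure(
    list(genotype = as.character(genotype), plants = as.character(plants),
         weeks = weeks, counts = counts, organ = organ),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %s: %d plants x %d weeks (%d-%d), organ %s\n",
              x$genotype, nrow(x$counts), ncol(x$counts),
              min(x$weeks), max(x$weeks), x$organ))
  invisible(x)
}

#' Read weekly count panels from a long-format table
#'
#' Reads a CSV/TSV file with one row per (plant, week) observation and builds
#' one [genotype_panel] per genotype. Plants whose weeks do not cover the
#' genotype's full contiguous observation window are dropped with a warning;
#' the model requires synchronous, gap-free series. Plant ordering within a
#' panel is lexicographic, so loading is deterministic.
#'
#' @param path path to a delimited text file with a header row and columns
#'   `genotype`, `plant`, `week` and a count column (`count`,
#'   `n_inflorescences` or `n_stolons` depending on `organ`). The delimiter
#'   (comma or tab) is sniffed from the header line.
#' @param organ which organ column to read.
#' @return Named list of [genotype_panel] objects, one per genotype, in
#'   lexicographic genotype order.
#' @export
load_panel <- function(path, organ = c("inflorescence", "stolon")) {
  organ <- match.arg(organ)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("genotype", "plant", "week")
  if (!all(need %in% names(df)))
    stop("input must have columns genotype, plant, week")
  count_col <- switch(organ,
                      inflorescence = c("n_inflorescences", "count"),
                      stolon = c("n_stolons", "count"))
  count_col <- count_col[count_col %in% names(df)][1]
  if (is.na(count_col))
    stop("no count column found for organ '", organ, "'")
  df <- df[!is.na(df[[count_col]]), , drop = FALSE]
  if (any(df[[count_col]] < 0))
    stop("negative count at row(s): ",
         paste(utils::head(which(df[[count_col]] < 0)), collapse = ", "))
  key <- paste(df$genotype, df$plant, df$week)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate observation for genotype %s, plant %s, week %s",
                 d$genotype, d$plant, d$week))
  }
  out <- list()
  for (g in sort(unique(as.character(df$genotype)))) {
    sub <- df[df$genotype == g, , drop = FALSE]
    weeks <- seq(min(sub$week), max(sub$week))
    keep <- list()
    dropped <- character()
    for (p in sort(unique(as.character(sub$plant)))) {
      rows <- sub[sub$plant == p, , drop = FALSE]
      rows <- rows[order(rows$week), , drop = FALSE]
      if (length(rows$week) == length(weeks) && all(rows$week == weeks)) {
        keep[[p]] <- rows[[count_col]]
      } else {
        dropped <- c(dropped, p)
      }
    }
    if (length(dropped))
      warning(sprintf("genotype %s: dropped %d plant(s) with missing weeks: %s",
                      g, length(dropped), paste(dropped, collapse = ", ")))
    if (!length(keep)) {
      warning(sprintf("genotype %s: no complete series, skipped", g))
      next
    }
    counts <- do.call(rbind, keep)
    out[[g]] <- genotype_panel(g, counts, weeks, plants = names(keep),
                               organ = organ)
  }
  out
}

#' Write panels back to a long-format CSV
#'
#' Inverse of [load_panel]: writes one row per (genotype, plant, week) with
#' the organ-appropriate count column, so `load_panel(write_panel(x))`
#' round-trips exactly.
#'
#' @param panels a [genotype_panel] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panels, path) {
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  organ <- panels[[1]]$organ
  col <- if (organ == "stolon") "n_stolons" else "n_inflorescences"
  rows <- lapply(panels, function(p) {
    data.frame(genotype = rep(p$genotype, length(p$counts)),
               plant = rep(p$plants, times = ncol(p$counts)),
               week = rep(p$weeks, each = nrow(p$counts)),
               count = as.vector(p$counts))
  })
  df <- do.call(rbind, rows)
  names(df)[4] <- col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode weekly counts as capped categories
#'
#' Maps raw weekly counts onto the categorical support `0..cap`, pooling all
#' values `>= cap` into the top category. With the default `cap = 5` this
#' gives the six-category encoding used for change-point model estimation
#' (large weekly counts are rare, so their probability masses cannot be
#' estimated separately). The uncapped counts are retained so phase means can
#' later be computed without grouping.
#'
#' @param panel a [genotype_panel].
#' @param cap largest category kept separate; values `>= cap` collapse into
#'   category `cap`.
#' @return An object of class `categorical_series` with fields `values`
#'   (P x T integer matrix in `0..cap`), `n_categories` (`cap + 1`), `cap`,
#'   `weeks`, `genotype`, `raw` (the uncapped matrix) and `organ`.
#' @examples
#' pan <- genotype_panel("G1", matrix(c(0, 3, 7, 5), 1), weeks = 16:19)
#' encode_counts(pan)$values   # 0 3 5 5
#' @export
encode_counts <- function(panel, cap = 5L) {
  stopifnot(inherits(panel, "genotype_panel"))
  cap <- as.integer(cap)
  if (cap < 1L) stop("cap must be >= 1")
  values <- pmin(panel$counts, cap)
  storage.mode(values) <- "integer"
  structure(
    list(values = values, n_categories = cap + 1L, cap = cap,
         weeks = panel$weeks, genotype = panel$genotype,
         plants = panel$plants, raw = panel$counts, organ = panel$organ),
    class = "categorical_series")
}

#' @export
print.categorical_series <- function(x, ...) {
  cat(sprintf("<categorical_series> %s: %d plants x %d weeks, %d categories (cap %d)\n",
              x$genotype, nrow(x$values), ncol(x$values),
              x$n_categories, x$cap))
  invisible(x)
}

#' Convert counts at uneven dates to weekly emergence rates
#'
#' Organ counts recorded at unevenly spaced visits (stolons are counted every
#' 2-4 weeks) are converted to weekly rates: the count accumulated since the
#' previous visit divided by the number of elapsed weeks. For the first
#' visit, the elapsed time is taken from `baseline_week` when given,
#' otherwise it defaults to one week. Evenly spaced weekly dates therefore
#' return the counts unchanged.
#'
#' @param dates strictly increasing integer calendar weeks of the visits.
#' @param counts numeric vector (one plant) or matrix (plants x dates) of
#'   counts newly accumulated at each visit since the previous one.
#' @param baseline_week optional week from which the first visit's interval
#'   is measured; must be `< dates[1]`.
#' @return An object of class `rate_series`: list with `dates`, `rates`
#'   (same shape as `counts`) and `elapsed` (weeks per interval).
#' @examples
#' to_rates(c(19, 21, 24), c(2, 2, 6))$rates   # 2 1 2
#' @export
to_rates <- function(dates, counts, baseline_week = NULL) {
  dates <- as.integer(dates)
  if (any(diff(dates) <= 0L)) stop("dates must be strictly increasing")
  first <- if (is.null(baseline_week)) 1L else {
    if (baseline_week >= dates[1]) stop("baseline_week must precede dates[1]")
    dates[1] - as.integer(baseline_week)
  }
  elapsed <- c(first, diff(dates))
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1) else as.matrix(counts)
  if (ncol(m) != length(dates)) stop("counts must have one column per date")
  if (any(m < 0)) stop("counts must be non-negative")
  rates <- sweep(m, 2L, elapsed, `/`)
  if (vec) rates <- drop(rates)
  structure(list(dates = dates, rates = rates, elapsed = elapsed),
            class = "rate_series")
}

#' Read a genotype-marker presence table
#'
#' Reads a table with columns `genotype`, `marker`, `state`, where state `H`
#' codes presence of the marker allele, `A` absence, and any other value is
#' treated as unknown.
#'
#' @param path delimited text file (comma or tab).
#' @return data.frame with columns `genotype`, `marker`,
#'   `state` in `{H, A, unknown}`.
#' @export
load_marker_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("genotype", "marker", "state") %in% names(df)))
    stop("marker table must have columns genotype, marker, state")
  df$state[!df$state %in% c("H", "A")] <- "unknown"
  df[c("genotype", "marker", "state")]
}

#' Total number of observations across panels
#'
#' The cumulative sample size Sum of P_g x T_g over panels: the quantity that
#' justifies direct estimation of category masses (e.g. 709 complete series
#' of length 28 give 19 852 observations).
#'
#' @param panels a [genotype_panel] or list of them.
#' @return integer observation count.
#' @export
cumulative_observations <- function(panels) {
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  sum(vapply(panels, function(p) length(p$counts), integer(1)))
}
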