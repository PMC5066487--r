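## Downstream statistics: flowering-runnering correlations on emergence
## rates, the single-marker t-test on late-phase flowering, end-of-season
## organ summaries and the between-genotype ANOVA. The tests themselves are
## standard and go through stats::cor.test / t.test / aov.

#' Correlation between inflorescence and stolon emergence rates
#'
#' Spearman (default) or Pearson correlation between paired inflorescence
#' and stolon weekly emergence rates at the (sparser) stolon measurement
#' dates. Pairs are formed either from the per-date means over plants
#' (`level = "mean"`, matching how pooled rate profiles are usually
#' displayed) or from every plant-date combination (`level = "plant"`).
#' Plain numeric vectors are accepted as already-paired observations.
#' Spearman uses average ranks for ties and a large-sample p-value.
#'
#' @param infl,stolon `rate_series` objects over the same dates (or paired
#'   numeric vectors).
#' @param dates optional subset of dates to keep (e.g. the perpetual
#'   flowering window `c(26, 29, 32, 35, 39, 43)`).
#' @param method `"spearman"` or `"pearson"`.
#' @param level pair per-date means or per-plant observations.
#' @param on_constant behaviour when one variable is constant (rank
#'   correlation undefined): `"error"` or `"zero"` (0 with a warning).
#' @return list of class `correlation_result`: `method`, `coefficient`,
#'   `p_value`, `n`.
#' @export
rate_correlation <- function(infl, stolon, dates = NULL,
                             method = c("spearman", "pearson"),
                             level = c("mean", "plant"),
                             on_constant = c("error", "zero")) {
  method <- match.arg(method)
  level <- match.arg(level)
  on_constant <- match.arg(on_constant)
  pair <- function(obj) {
    if (inherits(obj, "rate_series")) {
      r <- obj$rates
      if (is.null(dim(r))) r <- matrix(r, nrow = 1)
      keep <- if (is.null(dates)) seq_along(obj$dates)
      else which(obj$dates %in% dates)
      r <- r[, keep, drop = FALSE]
      if (level == "mean") colMeans(r) else as.vector(r)
    } else as.numeric(obj)
  }
  x <- pair(infl)
  y <- pair(stolon)
  if (length(x) != length(y)) stop("series must give the same number of pairs")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (on_constant == "error")
      stop("correlation undefined: one variable is constant")
    warning("one variable is constant; reporting coefficient 0")
    return(structure(list(method = method, coefficient = 0,
                          p_value = NA_real_, n = length(x)),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method,
                 coefficient = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s rho = %.3f (p = %.3g, n = %d)\n",
              x$method, x$coefficient, x$p_value, x$n))
  invisible(x)
}

#' Single-marker effect on a quantitative trait
#'
#' Two-sample Student's t-test (pooled variance by default; Welch via
#' `var_equal = FALSE`) comparing a trait -- typically the cumulative number
#' of inflorescences emerged during the late perpetual-flowering phase --
#' between plants whose genotype carries the marker allele (state `H`) and
#' those without it (state `A`). The reported `difference` is oriented as
#' `mean(A) - mean(H)`, so a locus whose absent allele boosts late
#' flowering shows a positive difference.
#'
#' @param trait data.frame with columns `genotype` and `value` (one row per
#'   plant or per genotype observation).
#' @param markers data.frame with columns `genotype`, `marker`, `state`
#'   (see [load_marker_table]).
#' @param marker marker identifier to test.
#' @param var_equal use pooled variance (classic Student) when `TRUE`.
#' @return list of class `marker_effect`: `marker`, `mean_H`, `mean_A`,
#'   `difference` (A - H), `t`, `p_value`, `n_H`, `n_A`. On degenerate
#'   (zero-variance) input `t` and `p_value` are `NA` with a warning.
#' @export
marker_effect_test <- function(trait, markers, marker, var_equal = TRUE) {
  stopifnot(all(c("genotype", "value") %in% names(trait)))
  mk <- markers[markers$marker == marker, , drop = FALSE]
  if (!nrow(mk)) stop("marker '", marker, "' not found in marker table")
  state <- mk$state[match(trait$genotype, mk$genotype)]
  vH <- trait$value[state == "H" & !is.na(state)]
  vA <- trait$value[state == "A" & !is.na(state)]
  if (length(vH) < 2 || length(vA) < 2)
    stop("both marker classes need at least 2 observations")
  tt <- tryCatch(stats::t.test(vA, vH, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt))
    warning("degenerate (constant) trait values; t and p set to NA")
  structure(list(marker = marker,
                 mean_H = mean(vH), mean_A = mean(vA),
                 difference = mean(vA) - mean(vH),
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value,
                 n_H = length(vH), n_A = length(vA)),
            class = "marker_effect")
}

#' @export
print.marker_effect <- function(x, ...) {
  cat(sprintf(
    "<marker_effect> %s: mean(A) = %.2f (n=%d), mean(H) = %.2f (n=%d), A-H = %.2f, t = %.2f, p = %.3g\n",
    x$marker, x$mean_A, x$n_A, x$mean_H, x$n_H, x$difference, x$t, x$p_value))
  invisible(x)
}

#' End-of-season organ count summaries
#'
#' Per-genotype (and optionally per-group) means and standard deviations of
#' the final numbers of inflorescences, stolons and crowns, plus their
#' cumulative total per plant -- the number of meristems activated during
#' the season. Group aggregates pool plants, not genotype means.
#'
#' @param end_table data.frame with columns `genotype`, `plant`,
#'   `n_inflorescences`, `n_stolons`, `n_crowns`.
#' @param grouping optional named character vector mapping genotype to a
#'   group label (e.g. from [classify_genotypes]).
#' @return list with data.frames `genotype` and (when grouping is supplied)
#'   `group`; columns are mean/SD per organ and for the cumulative count,
#'   plus `n_plants`.
#' @export
season_summary <- function(end_table, grouping = NULL) {
  need <- c("genotype", "plant", "n_inflorescences", "n_stolons", "n_crowns")
  stopifnot(all(need %in% names(end_table)))
  et <- end_table
  et$cumulative <- et$n_inflorescences + et$n_stolons + et$n_crowns
  summarise <- function(df, by) {
    agg <- function(f) stats::aggregate(
      df[c("n_inflorescences", "n_stolons", "n_crowns", "cumulative")],
      by = df[by], FUN = f)
    m <- agg(mean); s <- agg(stats::sd)
    names(m)[-1] <- paste0(names(m)[-1], "_mean")
    names(s)[-1] <- paste0(names(s)[-1], "_sd")
    out <- merge(m, s, by = by)
    n <- stats::aggregate(list(n_plants = df$plant), by = df[by], length)
    merge(out, n, by = by)
  }
  res <- list(genotype = summarise(et, "genotype"))
  if (!is.null(grouping)) {
    et$group <- grouping[et$genotype]
    res$group <- summarise(et[!is.na(et$group), , drop = FALSE], "group")
  }
  res
}

#' One-way ANOVA of a trait across genotypes
#'
#' Fixed-effects one-way analysis of variance testing whether genotype
#' means differ (e.g. season inflorescence totals within a flowering-
#' pattern group).
#'
#' @param values numeric trait vector.
#' @param groups factor or character vector of genotype labels, same length.
#' @return list with `F`, `p_value`, `df_between`, `df_within`. When all
#'   observations are identical the F statistic is reported as 0 with a
#'   warning.
#' @export
group_mean_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  if (stats::sd(values) == 0) {
    warning("all observations identical; F reported as 0")
    return(list(F = 0, p_value = NA_real_,
                df_between = nlevels(groups) - 1L,
                df_within = length(values) - nlevels(groups)))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       df_between = tab$Df[1], df_within = tab$Df[2])
}
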