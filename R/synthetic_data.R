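## Seeded generator of synthetic panels with the statistical structure the
## segmentation model assumes: piecewise-stationary categorical weekly
## counts, synchronous change points shared by the plants of a genotype
## (optionally jittered per plant), a binary marker controlling the presence
## of the late intense flowering phase, and stolon emergence negatively
## coupled to flowering through a shared weekly budget.

## Right-skewed categorical distribution on `support` with a prescribed
## mean: a Poisson truncated to the support, with its rate solved so the
## truncated mean matches exactly. Gives mode 0 for means < 1 and mode 1
## for means in [1, 2), the shapes seen in within-phase count histograms.
phase_pmf <- function(mean, support = 0:8) {
  stopifnot(mean >= 0, mean < max(support))
  if (mean == 0) {
    p <- numeric(length(support)); p[1] <- 1
    return(p)
  }
  trunc_mean <- function(lambda) {
    p <- stats::dpois(support, lambda)
    sum(support * p) / sum(p)
  }
  lambda <- stats::uniroot(function(l) trunc_mean(l) - mean,
                           interval = c(1e-8, 50), tol = 1e-12)$root
  p <- stats::dpois(support, lambda)
  p / sum(p)
}

#' Configuration of the synthetic panel generator
#'
#' Defines the study conditions the generator emulates: panels of plants
#' observed weekly over weeks 16-43, with genotype classes
#' \describe{
#'   \item{three_phase}{autumn-initiated flowering (AIF), flowering pause,
#'     one stationary perpetual flowering (PF) phase; change points at
#'     weeks 19|20 and 24|25; phase means 0.45 / 0.10 / 0.92.}
#'   \item{four_phase}{AIF, pause, then two PF phases of increasing
#'     intensity; change points 18|19, 24|25, 30|31; means
#'     0.45 / 0.10 / 0.92 / 1.65.}
#'   \item{seasonal}{AIF then near-zero flowering (seasonal habit).}
#' }
#' Weekly counts are drawn i.i.d. within a phase from right-skewed
#' categorical distributions on `support` (default 0..8, so downstream
#' capping at 5 is exercised). A binary marker follows the pattern: absence
#' (A) goes with the four-phase pattern and presence (H) with the
#' three-phase pattern, concordant with probability `penetrance`.
#'
#' @param n_genotypes named integer vector: genotypes per class, e.g.
#'   `c(three_phase = 5, four_phase = 5, seasonal = 0)`.
#' @param plants_per_genotype plants per genotype (recycled over genotypes).
#' @param weeks observation weeks (contiguous).
#' @param change_weeks per-class calendar weeks at which each phase after
#'   the first starts.
#' @param phase_means per-class mean weekly counts, one per phase.
#' @param support raw count support for the per-phase distributions.
#' @param theta optional per-class list of explicit per-phase probability
#'   rows over `support`, overriding `phase_means`.
#' @param jitter_probs probabilities of a per-plant change-point shift of
#'   -1, 0, +1 weeks (default: no jitter, the model-faithful case).
#' @param penetrance probability that a genotype's marker state is
#'   concordant with its flowering class.
#' @param marker_id marker name used in the emitted marker table.
#' @param stolon_dates sparse stolon measurement weeks.
#' @param stolon_budget shared weekly organ budget: stolon propensity is
#'   `max(0, budget - weekly inflorescence count)` scaled by habit.
#' @param stolon_scale named scales for perpetual (`PF`) and seasonal
#'   (`SF`) habits; SF plants runner much more.
#' @param crown_means per-class mean end-of-season crown counts.
#' @param seed integer seed; fully determines all sampled output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genotypes = c(three_phase = 0L, four_phase = 1L, seasonal = 0L),
    plants_per_genotype = 30L,
    weeks = 16:43,
    change_weeks = list(three_phase = c(20L, 25L),
                        four_phase = c(19L, 25L, 31L),
                        seasonal = 20L),
    phase_means = list(three_phase = c(0.45, 0.10, 0.92),
                       four_phase = c(0.45, 0.10, 0.92, 1.65),
                       seasonal = c(0.45, 0.02)),
    support = 0:8,
    theta = NULL,
    jitter_probs = c(0, 1, 0),
    penetrance = 1,
    marker_id = "EMFv020_146",
    stolon_dates = c(19L, 21L, 23L, 26L, 29L, 32L, 35L, 39L, 43L),
    stolon_budget = 2.5,
    stolon_scale = c(PF = 0.15, SF = 0.45),
    crown_means = c(three_phase = 3.8, four_phase = 6.7, seasonal = 4.6),
    seed = 1L) {
  classes <- c("three_phase", "four_phase", "seasonal")
  n_genotypes <- n_genotypes[intersect(names(n_genotypes), classes)]
  stopifnot(length(n_genotypes) >= 1, all(n_genotypes >= 0),
            sum(n_genotypes) >= 1)
  weeks <- as.integer(weeks)
  if (any(diff(weeks) != 1L)) stop("weeks must be contiguous")
  if (abs(sum(jitter_probs) - 1) > 1e-9 || length(jitter_probs) != 3)
    stop("jitter_probs must be 3 probabilities summing to 1")
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  if (is.null(theta)) {
    theta <- lapply(phase_means, function(m)
      do.call(rbind, lapply(m, phase_pmf, support = support)))
  } else {
    theta <- lapply(theta, function(th) {
      th <- as.matrix(th)
      if (ncol(th) != length(support)) stop("theta rows must span support")
      if (any(th < 0) || any(abs(rowSums(th) - 1) > 1e-9))
        stop("theta rows must be probability vectors")
      th
    })
  }
  for (cl in names(n_genotypes)) {
    if (n_genotypes[[cl]] == 0) next
    cw <- change_weeks[[cl]]
    if (nrow(theta[[cl]]) != length(cw) + 1L)
      stop("class ", cl, ": need one distribution per phase")
    if (any(cw <= min(weeks)) || any(cw > max(weeks)) ||
        is.unsorted(cw, strictly = TRUE))
      stop("class ", cl, ": change weeks must be strictly increasing inside the window")
  }
  structure(list(n_genotypes = n_genotypes,
                 plants_per_genotype = as.integer(plants_per_genotype),
                 weeks = weeks, change_weeks = change_weeks,
                 phase_means = phase_means, support = as.integer(support),
                 theta = theta, jitter_probs = jitter_probs,
                 penetrance = penetrance, marker_id = marker_id,
                 stolon_dates = as.integer(stolon_dates),
                 stolon_budget = stolon_budget, stolon_scale = stolon_scale,
                 crown_means = crown_means, seed = as.integer(seed)),
            class = "synthetic_config")
}

class_prefix <- c(three_phase = "TP", four_phase = "FP", seasonal = "SF")

#' Sample synthetic weekly count panels
#'
#' Draws one [genotype_panel] per genotype defined in the configuration,
#' together with the generating truth (class, number of phases, change
#' weeks, per-phase distributions, marker state, per-plant jitter shifts).
#' Output is fully determined by `config$seed`.
#'
#' @param config a [synthetic_config].
#' @return list with `panels` (named list of [genotype_panel]), `truth`
#'   (named list per genotype) and `markers` (data.frame
#'   `genotype`/`marker`/`state`).
#' @export
sample_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  weeks <- config$weeks
  T <- length(weeks)
  gens <- unlist(lapply(names(config$n_genotypes), function(cl)
    if (config$n_genotypes[[cl]] > 0)
      sprintf("%s_%02d", class_prefix[[cl]], seq_len(config$n_genotypes[[cl]]))
    else character(0)))
  cls <- rep(names(config$n_genotypes), config$n_genotypes)
  P_each <- rep_len(config$plants_per_genotype, length(gens))
  panels <- list(); truth <- list(); mk_state <- character(length(gens))
  for (i in seq_along(gens)) {
    cl <- cls[i]; P <- P_each[i]
    cw <- as.integer(config$change_weeks[[cl]])
    th <- config$theta[[cl]]
    J <- nrow(th)
    concordant <- stats::runif(1) <= config$penetrance
    pattern_state <- if (cl == "four_phase") "A" else "H"
    mk_state[i] <- if (concordant) pattern_state
    else setdiff(c("A", "H"), pattern_state)
    shifts <- sample(c(-1L, 0L, 1L), P, replace = TRUE,
                     prob = config$jitter_probs)
    counts <- matrix(0L, P, T)
    for (p in seq_len(P)) {
      cw_p <- pmin(pmax(cw + shifts[p], min(weeks) + 1L), max(weeks))
      phase <- findInterval(weeks, c(min(weeks), cw_p))
      for (j in seq_len(J)) {
        idx <- which(phase == j)
        if (length(idx))
          counts[p, idx] <- sample(config$support, length(idx),
                                   replace = TRUE, prob = th[j, ])
      }
    }
    panels[[gens[i]]] <- genotype_panel(gens[i], counts, weeks,
                                        plants = sprintf("p%02d", seq_len(P)))
    truth[[gens[i]]] <- list(class = cl, J = J, change_weeks = cw,
                             theta = th, marker = mk_state[i],
                             shifts = shifts)
  }
  markers <- data.frame(genotype = gens, marker = config$marker_id,
                        state = mk_state)
  list(panels = panels, truth = truth, markers = markers)
}

#' Sample stolon emergence coupled to a flowering panel
#'
#' Weekly stolon counts are Poisson with propensity
#' `max(0, budget - weekly inflorescence count) * scale(habit)`, so plants
#' that flower more runner less by construction; seasonal-habit plants get
#' the much larger `SF` scale. Weekly counts are then accumulated to the
#' sparse stolon measurement dates and converted to weekly rates.
#'
#' @param config a [synthetic_config].
#' @param sampled output of [sample_panel] for the same config.
#' @return named list per genotype with `counts` (plants x dates matrix of
#'   counts accumulated since the previous date) and `rates`
#'   (a `rate_series`).
#' @export
sample_stolons <- function(config, sampled) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  weeks <- config$weeks
  dates <- config$stolon_dates
  if (any(!dates %in% weeks)) stop("stolon dates must lie inside the weeks")
  ## week w falls in bin k iff dates[k-1] < w <= dates[k]
  interval <- findInterval(weeks - 1L, dates) + 1L
  out <- list()
  for (g in names(sampled$panels)) {
    pan <- sampled$panels[[g]]
    habit <- if (sampled$truth[[g]]$class == "seasonal") "SF" else "PF"
    lambda <- pmax(config$stolon_budget - pan$counts, 0) *
      config$stolon_scale[[habit]]
    weekly <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
    counts <- vapply(seq_along(dates), function(k)
      rowSums(weekly[, interval == k, drop = FALSE]),
      numeric(nrow(weekly)))
    counts <- matrix(counts, nrow = nrow(weekly),
                     dimnames = list(pan$plants, dates))
    out[[g]] <- list(counts = counts,
                     rates = to_rates(dates, counts,
                                      baseline_week = min(weeks) - 1L))
  }
  out
}

#' Sample a complete synthetic study
#'
#' One call produces everything the analysis pipeline consumes: weekly
#' inflorescence panels, sparse stolon counts and rates, an end-of-season
#' organ count table (inflorescence and stolon season totals from the
#' sampled series, crowns Poisson at the class means), the marker table and
#' the generating truth.
#'
#' @param config a [synthetic_config].
#' @return list with `panels`, `stolons`, `end_of_season`, `markers`,
#'   `truth`.
#' @export
sample_study <- function(config) {
  sampled <- sample_panel(config)
  stolons <- sample_stolons(config, sampled)
  set.seed(config$seed + 2L)
  rows <- lapply(names(sampled$panels), function(g) {
    pan <- sampled$panels[[g]]
    cl <- sampled$truth[[g]]$class
    data.frame(genotype = g, plant = pan$plants,
               n_inflorescences = rowSums(pan$counts),
               n_stolons = rowSums(stolons[[g]]$counts),
               n_crowns = stats::rpois(nrow(pan$counts),
                                       config$crown_means[[cl]]))
  })
  list(panels = sampled$panels, stolons = stolons,
       end_of_season = do.call(rbind, rows),
       markers = sampled$markers, truth = sampled$truth)
}
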