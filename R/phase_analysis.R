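## Model-selection policy and genotype-comparison layer. ICL gives an
## indicative number of phases for short series; the policy codifies the
## manual downgrades applied in practice: re-segment with one fewer phase
## when the optimum contains a too-short phase, and when two markedly
## different segmentations are nearly equally probable.

#' Selection policy for the number of flowering phases
#'
#' Tunable thresholds for [select_num_phases]. `min_phase_weeks` is the
#' shortest admissible phase (1-week phases are read as between-plant
#' asynchronism, not real phases); a rival segmentation counts as a genuine
#' ambiguity when its posterior is at least `ambiguity_ratio` times the
#' best one and some change point differs by at least `ambiguity_shift`
#' weeks.
#'
#' @param jmax largest number of phases scored by ICL.
#' @param min_phase_weeks minimum admissible phase length in weeks.
#' @param ambiguity_ratio posterior ratio (second best / best) above which a
#'   rival segmentation is considered serious.
#' @param ambiguity_shift minimum change-point displacement (weeks) for a
#'   rival to count as "markedly different".
#' @return list of class `selection_policy`.
#' @export
selection_policy <- function(jmax = 6L, min_phase_weeks = 2L,
                             ambiguity_ratio = 0.5, ambiguity_shift = 3L) {
  stopifnot(jmax >= 1, min_phase_weeks >= 1,
            ambiguity_ratio > 0, ambiguity_shift >= 1)
  structure(list(jmax = as.integer(jmax),
                 min_phase_weeks = as.integer(min_phase_weeks),
                 ambiguity_ratio = ambiguity_ratio,
                 ambiguity_shift = as.integer(ambiguity_shift)),
            class = "selection_policy")
}

## Does the rival segmentation differ from the best by a large change-point
## shift? Compared change point by change point (same J for both).
markedly_different <- function(cps_a, cps_b, shift) {
  length(cps_a) && any(abs(cps_a - cps_b) >= shift)
}

#' Select the number of flowering phases for one genotype
#'
#' Applies the model-selection policy on top of the ICL criterion. Starting
#' from the ICL-preferred `J`:
#' \enumerate{
#'   \item while the optimal segmentation contains a phase shorter than
#'     `min_phase_weeks`, refit with one phase fewer (flag
#'     `one_week_phase`);
#'   \item if the second-best segmentation at the current `J` has posterior
#'     at least `ambiguity_ratio` times the best and displaces some change
#'     point by at least `ambiguity_shift` weeks, flag `ambiguous`, drop one
#'     more phase, and re-apply step 1.
#' }
#' Both the ICL-preferred and the finally selected `J` are reported so the
#' manual selection path stays auditable.
#'
#' @param series a `categorical_series` for one genotype.
#' @param policy a [selection_policy].
#' @inheritParams icl
#' @return Object of class `genotype_classification`: list with
#'   `genotype_id`, `icl_J`, `selected_J`, `flags` (subset of
#'   `c("one_week_phase", "ambiguous")`), `model` (the selected
#'   `phase_model`), `phase_summaries` (calendar limits and uncapped means),
#'   `posterior_of_optimal`, `posterior_of_model`, and the full `report`.
#' @export
select_num_phases <- function(series, policy = selection_policy(),
                              d = NULL, penalty = c("logT", "logPT")) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(series, "categorical_series"))
  T <- ncol(series$values)
  rep <- segment_series(series, Jmax = min(policy$jmax, T),
                        d = d, penalty = penalty)
  cost <- cost_matrix(series)
  flags <- character(0)

  shortest_phase <- function(J)
    min(phase_limits(optimal_segmentation(series, J, cost = cost)$segmentation)$length_weeks)
  drop_short <- function(J) {
    while (J > 1 && shortest_phase(J) < policy$min_phase_weeks) {
      flags <<- union(flags, "one_week_phase")
      J <- J - 1L
    }
    J
  }

  J <- drop_short(rep$icl_J)
  if (J > 1) {
    top2 <- top_segmentations(series, J, 2L, cost = cost)
    if (nrow(top2) >= 2 &&
        top2$posterior[2] >= policy$ambiguity_ratio * top2$posterior[1]) {
      cps <- as.matrix(top2[, grep("^cp", names(top2)), drop = FALSE])
      if (markedly_different(cps[1, ], cps[2, ], policy$ambiguity_shift)) {
        flags <- union(flags, "ambiguous")
        J <- drop_short(J - 1L)
      }
    }
  }

  model <- optimal_segmentation(series, J, cost = cost)
  lim <- phase_limits(model$segmentation)
  lim$mean_weekly_count <- model$phase_means
  structure(list(
    genotype_id = series$genotype,
    icl_J = rep$icl_J,
    selected_J = J,
    flags = flags,
    model = model,
    phase_summaries = lim,
    posterior_of_optimal = segmentation_posterior(series, model, cost = cost),
    posterior_of_model = unname(rep$model_posteriors[J]),
    report = rep), class = "genotype_classification")
}

#' @export
print.genotype_classification <- function(x, ...) {
  cat(sprintf("<genotype_classification> %s: selected J = %d (ICL J = %d)%s\n",
              x$genotype_id, x$selected_J, x$icl_J,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  print(transform(x$phase_summaries,
                  mean_weekly_count = round(mean_weekly_count, 3)),
        row.names = FALSE)
  cat(sprintf("posterior of segmentation %.3f, of model %.3f\n",
              x$posterior_of_optimal, x$posterior_of_model))
  invisible(x)
}

#' Group genotypes by flowering pattern
#'
#' Assigns each classified genotype to `three_phase`, `four_phase` or
#' `intermediate`. Genotypes flagged `ambiguous` go to `intermediate`.
#' Among `selected_J = 4` genotypes the mean weekly count of the final
#' phase separates "true" four-phase patterns (a late phase of high
#' intensity, means around 1.4-1.9) from mere refinements of a stationary
#' perpetual-flowering phase (late means around 1.1): only genotypes with a
#' late mean at or above `late_mean_threshold` are grouped `four_phase`.
#'
#' @param classifications list of `genotype_classification` objects from
#'   [select_num_phases].
#' @param late_mean_threshold minimum last-phase mean weekly count for a
#'   genuine four-phase pattern.
#' @return data.frame with one row per genotype: `genotype`, `selected_J`,
#'   `icl_J`, `late_mean`, `flags`, `group`.
#' @export
classify_genotypes <- function(classifications, late_mean_threshold = 1.3) {
  if (inherits(classifications, "genotype_classification"))
    classifications <- list(classifications)
  if (!length(classifications))
    return(data.frame(genotype = character(0), selected_J = integer(0),
                      icl_J = integer(0), late_mean = numeric(0),
                      flags = character(0), group = character(0)))
  rows <- lapply(classifications, function(cl) {
    late <- cl$model$phase_means[cl$selected_J]
    group <- if ("ambiguous" %in% cl$flags) "intermediate"
    else if (cl$selected_J == 4 && late >= late_mean_threshold) "four_phase"
    else if (cl$selected_J == 4) "three_phase"   # refinement of a stationary PF phase
    else if (cl$selected_J == 3) "three_phase"
    else "intermediate"
    data.frame(genotype = cl$genotype_id, selected_J = cl$selected_J,
               icl_J = cl$icl_J, late_mean = late,
               flags = paste(cl$flags, collapse = ";"), group = group)
  })
  do.call(rbind, rows)
}

#' Consensus segmentation of pooled genotypes
#'
#' Stacks the plants of all given genotypes into one multivariate series
#' (e.g. 276 plants of the four-phase genotypes over 28 weeks) and returns
#' its optimal `J`-phase segmentation. Because the profile likelihood only
#' depends on pooled category frequencies, the consensus of several copies
#' of the same panel equals the single-panel optimum.
#'
#' @param series_list list of `categorical_series` sharing the same week
#'   labels and cap.
#' @param J number of consensus phases.
#' @return A `phase_model` for the pooled series, with
#'   `posterior` (posterior probability of the consensus segmentation) and
#'   `n_plants` fields added.
#' @export
consensus_segmentation <- function(series_list, J) {
  if (inherits(series_list, "categorical_series"))
    series_list <- list(series_list)
  stopifnot(length(series_list) >= 1)
  wk <- series_list[[1]]$weeks
  cap <- series_list[[1]]$cap
  for (s in series_list) {
    if (!identical(s$weeks, wk)) stop("all series must share the same weeks")
    if (s$cap != cap) stop("all series must share the same cap")
  }
  pooled <- structure(list(
    values = do.call(rbind, lapply(series_list, `[[`, "values")),
    n_categories = cap + 1L, cap = cap, weeks = wk,
    genotype = "consensus",
    plants = unlist(lapply(series_list, function(s)
      paste(s$genotype, s$plants, sep = ":"))),
    raw = do.call(rbind, lapply(series_list, `[[`, "raw")),
    organ = series_list[[1]]$organ), class = "categorical_series")
  cost <- cost_matrix(pooled)
  m <- optimal_segmentation(pooled, J, cost = cost)
  m$posterior <- segmentation_posterior(pooled, m, cost = cost)
  m$n_plants <- nrow(pooled$values)
  m
}

#' Per-plant cumulative counts within consensus phases
#'
#' For every plant, sums the uncapped weekly counts falling inside each
#' phase of a (consensus) segmentation. Phase totals add up to the
#' plant's season total, so the table is a lossless split of end-of-season
#' counts along the phase boundaries; it is the trait table used for
#' phase-specific association tests.
#'
#' @param panels a [genotype_panel] or list of them, all covering the
#'   segmentation's window.
#' @param seg a [segmentation] (e.g. from [consensus_segmentation]'s
#'   `$segmentation`).
#' @return data.frame with columns `genotype`, `plant`, `phase1..phaseJ`,
#'   `total`.
#' @export
phase_trait_table <- function(panels, seg) {
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  starts <- c(1L, seg$change_points)
  ends <- c(seg$change_points - 1L, seg$T)
  rows <- lapply(panels, function(p) {
    if (ncol(p$counts) != seg$T)
      stop("segmentation window does not match panel ", p$genotype)
    ph <- vapply(seq_along(starts), function(j)
      rowSums(p$counts[, starts[j]:ends[j], drop = FALSE]), numeric(nrow(p$counts)))
    ph <- matrix(ph, nrow = nrow(p$counts))
    df <- data.frame(genotype = p$genotype, plant = p$plants)
    for (j in seq_along(starts)) df[[paste0("phase", j)]] <- ph[, j]
    df$total <- rowSums(ph)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
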