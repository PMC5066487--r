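## Multiple change-point engine for synchronous categorical series.
##
## A segmentation of the T measurement dates into J contiguous phases is
## scored by its profile log-likelihood: within each phase the category
## probabilities are the ML frequencies pooled over all plants and weeks of
## the phase. All quantities below (optimal segmentation, sum over all
## segmentations, entropy, posteriors, profiles, N-best) are exact; sums are
## carried in log-space.

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Table of all segment profile log-likelihoods
#'
#' Computes [segment_cost] for every window `u..v` at once from cumulative
#' per-category counts, in `O(C T^2)`. All engine functions accept this
#' matrix through their `cost` argument to avoid recomputation.
#'
#' @param series a `categorical_series`.
#' @return `T x T` matrix; entry `[u, v]` (for `u <= v`) is the profile
#'   log-likelihood of segment `u..v`, `NA` below the diagonal.
#' @export
cost_matrix <- function(series) {
  stopifnot(inherits(series, "categorical_series"))
  vals <- series$values
  C <- series$n_categories
  T <- ncol(vals)
  P <- nrow(vals)
  cum <- matrix(0, C, T + 1L)
  for (t in seq_len(T))
    cum[, t + 1L] <- cum[, t] + tabulate(vals[, t] + 1L, nbins = C)
  cost <- matrix(NA_real_, T, T)
  for (u in seq_len(T)) {
    n <- cum[, (u + 1L):(T + 1L), drop = FALSE] - cum[, u]
    term <- n * log(n)
    term[n == 0] <- 0
    ntot <- P * seq_len(T - u + 1L)
    cost[u, u:T] <- colSums(term) - ntot * log(ntot)
  }
  cost
}

#' Profile log-likelihood of one segment
#'
#' Scores the segment of a categorical series spanning time indices
#' `u..v` (1-based, inclusive) with the plug-in ML categorical distribution:
#' with `n_c` occurrences of category `c` among the pooled `P * (v-u+1)`
#' observations and `n` their total, returns `sum_c n_c log(n_c / n)`
#' (conventions `0 log 0 = 0`). Always `<= 0`.
#'
#' @param series a `categorical_series` from [encode_counts].
#' @param u,v segment bounds as time indices in `1..T`, `u <= v`.
#' @return segment profile log-likelihood (scalar).
#' @examples
#' pan <- genotype_panel("g", matrix(c(0, 1), 1), weeks = 1:2)
#' segment_cost(encode_counts(pan), 1, 2)  # 2 * log(1/2)
#' @export
segment_cost <- function(series, u, v) {
  T <- ncol(series$values)
  if (u < 1 || v > T || u > v) stop("need 1 <= u <= v <= T")
  vals <- series$values[, u:v, drop = FALSE]
  n <- tabulate(vals + 1L, nbins = series$n_categories)
  n <- n[n > 0]
  sum(n * log(n / sum(n)))
}

#' Number of segmentations of a series into contiguous phases
#'
#' A length-`T` series has `choose(T - 1, J - 1)` segmentations into `J`
#' non-empty contiguous phases (one per placement of the `J - 1` interior
#' change points). For 28 weekly dates this gives 351 three-phase and 2925
#' four-phase segmentations.
#'
#' @param T series length (number of measurement dates).
#' @param J number of phases.
#' @return integer count; 0 when `J > T`.
#' @examples
#' count_segmentations(28, 3)  # 351
#' count_segmentations(28, 4)  # 2925
#' @export
count_segmentations <- function(T, J) {
  if (J < 1 || T < 1) stop("need T >= 1, J >= 1")
  if (J > T) return(0)
  choose(T - 1, J - 1)
}

#' Enumerate all segmentations explicitly
#'
#' Lists every segmentation of `1..T` into `J` contiguous phases as a matrix
#' of interior change points (the time index at which each phase `2..J`
#' starts). Practical only for small `T`; used for exact small-sample
#' computations and as a cross-check of the closed-form count.
#'
#' @inheritParams count_segmentations
#' @return integer matrix with `choose(T-1, J-1)` rows and `J - 1` columns;
#'   a 1-row, 0-column matrix when `J = 1`.
#' @export
enumerate_segmentations <- function(T, J) {
  if (J > T) stop("J must be <= T")
  if (J == 1) return(matrix(integer(0), nrow = 1, ncol = 0))
  m <- t(utils::combn(2:T, J - 1))
  storage.mode(m) <- "integer"
  m
}

#' Segmentation of a series into contiguous phases
#'
#' Constructor for the `segmentation` class: `J` phases over time indices
#' `1..T`, delimited by strictly increasing interior change points (the
#' index at which each phase after the first starts).
#'
#' @param change_points integer vector of `J - 1` phase-start indices in
#'   `2..T`; empty for `J = 1`.
#' @param T series length.
#' @param weeks optional calendar-week labels (length `T`) for reporting.
#' @return `segmentation` object with fields `n_phases`, `change_points`,
#'   `T`, `weeks`.
#' @export
segmentation <- function(change_points, T, weeks = NULL) {
  change_points <- as.integer(change_points)
  T <- as.integer(T)
  if (length(change_points)) {
    if (is.unsorted(change_points, strictly = TRUE) ||
        any(change_points < 2L) || any(change_points > T))
      stop("change points must be strictly increasing within 2..T")
  }
  if (!is.null(weeks) && length(weeks) != T)
    stop("weeks must have length T")
  structure(list(n_phases = length(change_points) + 1L,
                 change_points = change_points, T = T, weeks = weeks),
            class = "segmentation")
}

#' Phase membership of each time index
#'
#' @param seg a [segmentation].
#' @return integer vector of length `T`; entry `t` is the phase index of
#'   time `t`.
#' @export
phase_of_time <- function(seg) {
  starts <- c(1L, seg$change_points)
  findInterval(seq_len(seg$T), starts)
}

#' Phase limits in calendar weeks
#'
#' @param seg a [segmentation] carrying week labels.
#' @return data.frame with columns `phase`, `first_week`, `last_week`,
#'   `length_weeks` (limits are inclusive, e.g. "16-19").
#' @export
phase_limits <- function(seg) {
  starts <- c(1L, seg$change_points)
  ends <- c(seg$change_points - 1L, seg$T)
  wk <- if (is.null(seg$weeks)) seq_len(seg$T) else seg$weeks
  data.frame(phase = seq_len(seg$n_phases),
             first_week = wk[starts], last_week = wk[ends],
             length_weeks = ends - starts + 1L)
}

#' @export
print.segmentation <- function(x, ...) {
  lim <- phase_limits(x)
  cat(sprintf("<segmentation> %d phase(s): %s\n", x$n_phases,
              paste(sprintf("%d-%d", lim$first_week, lim$last_week),
                    collapse = " | ")))
  invisible(x)
}

## Build the fitted phase model (theta, log-likelihood, uncapped means) for a
## given segmentation of a series.
fit_phase_model <- function(series, seg, cost = NULL) {
  if (is.null(cost)) cost <- cost_matrix(series)
  starts <- c(1L, seg$change_points)
  ends <- c(seg$change_points - 1L, seg$T)
  C <- series$n_categories
  theta <- matrix(0, seg$n_phases, C,
                  dimnames = list(NULL, 0:(C - 1L)))
  means <- numeric(seg$n_phases)
  ll <- 0
  for (j in seq_len(seg$n_phases)) {
    vals <- series$values[, starts[j]:ends[j], drop = FALSE]
    n <- tabulate(vals + 1L, nbins = C)
    theta[j, ] <- n / sum(n)
    means[j] <- mean(series$raw[, starts[j]:ends[j]])
    ll <- ll + cost[starts[j], ends[j]]
  }
  structure(list(segmentation = seg, theta = theta, log_likelihood = ll,
                 phase_means = means, genotype = series$genotype),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  lim <- phase_limits(x$segmentation)
  cat(sprintf("<phase_model> %s: %d phase(s), log-likelihood %.3f\n",
              if (is.null(x$genotype)) "" else x$genotype,
              x$segmentation$n_phases, x$log_likelihood))
  lim$mean_weekly_count <- round(x$phase_means, 3)
  print(lim, row.names = FALSE)
  invisible(x)
}

#' Optimal segmentation into J phases by dynamic programming
#'
#' Finds the segmentation of the series into `J` contiguous phases that
#' maximises the profile log-likelihood (the sum of [segment_cost] over
#' phases), by dynamic programming over (phase, time) in `O(T^2 J)` segment
#' evaluations. Ties are resolved deterministically towards the smallest
#' segment-start index at each backtracking step, so a constant series
#' yields change points `2, 3, ..., J`.
#'
#' @param series a `categorical_series`.
#' @param J number of phases, `1 <= J <= T`.
#' @param cost optional precomputed [cost_matrix] (internal reuse).
#' @return A `phase_model`: the optimal [segmentation], per-phase category
#'   probabilities `theta`, the maximised `log_likelihood`, and per-phase
#'   mean weekly counts computed on the uncapped counts.
#' @examples
#' pan <- genotype_panel("g", matrix(c(0, 0, 0, 3, 3, 3), 1), weeks = 1:6)
#' optimal_segmentation(encode_counts(pan), 2)$segmentation$change_points  # 4
#' @export
optimal_segmentation <- function(series, J, cost = NULL) {
  T <- ncol(series$values)
  J <- as.integer(J)
  if (J < 1 || J > T) stop("J must satisfy 1 <= J <= T")
  if (is.null(cost)) cost <- cost_matrix(series)
  F <- matrix(-Inf, J, T)
  ptr <- matrix(NA_integer_, J, T)
  F[1, ] <- cost[1, ]
  ptr[1, ] <- 1L
  if (J > 1) {
    for (j in 2:J) {
      for (t in j:T) {
        u <- j:t
        cand <- F[j - 1, u - 1L] + cost[cbind(u, t)]
        b <- which.max(cand)      # first maximum = smallest start u
        F[j, t] <- cand[b]
        ptr[j, t] <- u[b]
      }
    }
  }
  cps <- integer(0)
  t <- T
  for (j in J:1) {
    u <- ptr[j, t]
    if (j > 1) cps <- c(u, cps)
    t <- u - 1L
  }
  seg <- segmentation(cps, T, weeks = series$weeks)
  m <- fit_phase_model(series, seg, cost)
  m$log_likelihood <- F[J, T]
  m
}

## Forward log-sums: A[j, t] = log sum over all segmentations of prefix 1..t
## into exactly j phases of their profile likelihood.
forward_logsums <- function(cost, J) {
  T <- ncol(cost)
  A <- matrix(-Inf, J, T)
  A[1, ] <- cost[1, ]
  if (J > 1) {
    for (j in 2:J) {
      for (t in j:T) {
        u <- j:t
        A[j, t] <- logsumexp(A[j - 1, u - 1L] + cost[cbind(u, t)])
      }
    }
  }
  A
}

## Backward log-sums: B[j, t] = log sum over segmentations of suffix t..T
## into phases j..J (J - j + 1 segments).
backward_logsums <- function(cost, J) {
  T <- ncol(cost)
  B <- matrix(-Inf, J, T)
  B[J, ] <- cost[, T]
  if (J > 1) {
    for (j in (J - 1):1) {
      for (t in j:(T - (J - j))) {
        v <- t:(T - (J - j))
        B[j, t] <- logsumexp(cost[t, v] + B[j + 1, v + 1L])
      }
    }
  }
  B
}

## Exact posterior segment quantities for fixed J via forward-backward:
## log marginal, entropy, occupancy/entry profiles. The posterior weight of
## "phase j spans u..v" is exp(A[j-1,u-1] + cost[u,v] + B[j+1,v+1] - logM);
## the entropy uses H = logM - E[score(S)].
posterior_quantities <- function(cost, J, profiles = TRUE) {
  T <- ncol(cost)
  A <- forward_logsums(cost, J)
  B <- backward_logsums(cost, J)
  logM <- A[J, T]
  escore <- 0
  occ <- if (profiles) matrix(0, T, J) else NULL
  ent <- if (profiles) matrix(0, T, J) else NULL
  for (j in seq_len(J)) {
    umin <- j
    vmax <- T - (J - j)
    for (u in umin:vmax) {
      v <- u:vmax
      aprev <- if (j == 1) {
        if (u == 1) 0 else -Inf
      } else A[j - 1, u - 1L]
      if (!is.finite(aprev)) next
      bnext <- if (j == J) {
        ifelse(v == T, 0, -Inf)
      } else B[j + 1, v + 1L]
      lw <- aprev + cost[u, v] + bnext - logM
      w <- exp(lw)
      ok <- w > 0
      if (any(ok)) escore <- escore + sum(w[ok] * cost[u, v[ok]])
      if (profiles) {
        ent[u, j] <- sum(w)
        occ[u:vmax, j] <- occ[u:vmax, j] + rev(cumsum(rev(w)))
      }
    }
  }
  H <- max(0, logM - escore)
  list(log_marginal = logM, entropy = H, occupancy = occ, entry = ent)
}

#' Log-likelihood summed over all segmentations
#'
#' Computes `log L_J(x)`, the log of the sum over all
#' `choose(T-1, J-1)` segmentations into `J` phases of their profile
#' likelihoods, by a forward recursion in log-space. It always lies between
#' the optimal segmentation's log-likelihood and that value plus
#' `log count_segmentations(T, J)`.
#'
#' @inheritParams optimal_segmentation
#' @return scalar `log L_J(x)`.
#' @export
log_marginal <- function(series, J, cost = NULL) {
  T <- ncol(series$values)
  if (J < 1 || J > T) stop("J must satisfy 1 <= J <= T")
  if (is.null(cost)) cost <- cost_matrix(series)
  forward_logsums(cost, J)[J, T]
}

#' Entropy of the posterior distribution over segmentations
#'
#' Shannon entropy `H(S | X = x; J) = -sum_s P(s|x) log P(s|x)` of the
#' posterior over all `J`-phase segmentations, where
#' `P(s|x) = exp(score(s) - log L_J(x))`. Low entropy means the series
#' supports an unambiguous phase structure. Computed exactly, either by the
#' forward-backward decomposition (default, scales to long series) or by
#' explicit enumeration (small `T` cross-check).
#'
#' @inheritParams optimal_segmentation
#' @param method `"smoothing"` for the forward-backward computation,
#'   `"enumeration"` for the explicit sum over all segmentations.
#' @return entropy in nats, in `[0, log count_segmentations(T, J)]`.
#' @export
segmentation_entropy <- function(series, J,
                                 method = c("smoothing", "enumeration"),
                                 cost = NULL) {
  method <- match.arg(method)
  T <- ncol(series$values)
  if (J < 1 || J > T) stop("J must satisfy 1 <= J <= T")
  if (is.null(cost)) cost <- cost_matrix(series)
  if (method == "smoothing")
    return(posterior_quantities(cost, J, profiles = FALSE)$entropy)
  segs <- enumerate_segmentations(T, J)
  scores <- apply(segs, 1, function(cps) {
    starts <- c(1L, cps); ends <- c(cps - 1L, T)
    sum(cost[cbind(starts, ends)])
  })
  if (!nrow(segs)) scores <- cost[1, T]
  logM <- logsumexp(scores)
  p <- exp(scores - logM)
  max(0, -sum(ifelse(p > 0, p * log(p), 0)))
}

#' Integrated completed likelihood criterion
#'
#' Penalised model-selection criterion dedicated to segmentation:
#' `ICL_J = 2 log L_J(x) - d_J log T - 2 H(S | X = x; J)`.
#' The first term measures fit summed over all segmentations, the second
#' penalises the `d_J` free parameters, and the entropy term additionally
#' penalises models whose segmentation is ambiguous. By default
#' `d_J = (J - 1) + J (C - 1)`: the interior change points plus `C - 1` free
#' category probabilities per phase.
#'
#' @inheritParams optimal_segmentation
#' @param d optional override for the free-parameter count `d_J`.
#' @param penalty `"logT"` (the criterion as written, `log` of the number of
#'   measurement dates) or `"logPT"` (`log` of the cumulative number of
#'   observations `P * T`).
#' @return scalar ICL value (natural-log units).
#' @export
icl <- function(series, J, d = NULL, penalty = c("logT", "logPT"),
                cost = NULL) {
  penalty <- match.arg(penalty)
  T <- ncol(series$values)
  if (is.null(cost)) cost <- cost_matrix(series)
  q <- posterior_quantities(cost, J, profiles = FALSE)
  C <- series$n_categories
  if (is.null(d)) d <- (J - 1) + J * (C - 1)
  n <- if (penalty == "logT") T else length(series$values)
  2 * q$log_marginal - d * log(n) - 2 * q$entropy
}

#' Posterior probabilities of the candidate phase numbers
#'
#' Converts the ICL values for `J = 1..Jmax` into posterior model
#' probabilities `P(M_J | x) = exp(ICL_J / 2) / sum_K exp(ICL_K / 2)`,
#' computed stably in log-space.
#'
#' @inheritParams icl
#' @param Jmax largest number of phases considered.
#' @return numeric vector of length `Jmax` summing to 1, named by `J`.
#' @export
model_posteriors <- function(series, Jmax, d = NULL,
                             penalty = c("logT", "logPT"), cost = NULL) {
  penalty <- match.arg(penalty)
  T <- ncol(series$values)
  if (Jmax < 1 || Jmax > T) stop("Jmax must satisfy 1 <= Jmax <= T")
  if (is.null(cost)) cost <- cost_matrix(series)
  half <- vapply(seq_len(Jmax), function(J)
    icl(series, J, d = d, penalty = penalty, cost = cost) / 2, numeric(1))
  p <- exp(half - logsumexp(half))
  p <- p / sum(p)
  names(p) <- seq_len(Jmax)
  p
}

#' Posterior probability of a fitted segmentation
#'
#' Weight of the given segmentation among all `J`-phase segmentations:
#' `P(s | x; J) = exp(score(s) - log L_J(x))`. For the optimal segmentation
#' this is at least `1 / count_segmentations(T, J)`.
#'
#' @param series a `categorical_series`.
#' @param model a `phase_model` (e.g. from [optimal_segmentation]).
#' @inheritParams optimal_segmentation
#' @return probability in `(0, 1]`.
#' @export
segmentation_posterior <- function(series, model, cost = NULL) {
  J <- model$segmentation$n_phases
  exp(model$log_likelihood - log_marginal(series, J, cost = cost))
}

#' Top-N most probable segmentations
#'
#' Ranks segmentations into `J` phases by posterior probability using an
#' N-best dynamic programme: each (phase, time) cell keeps its `N` best
#' prefix scores with backpointers. The first entry always coincides with
#' [optimal_segmentation]; with `N >= count_segmentations(T, J)` the full
#' posterior distribution is returned and its probabilities sum to 1.
#'
#' @inheritParams optimal_segmentation
#' @param N number of segmentations requested.
#' @return data.frame with one row per returned segmentation: columns
#'   `rank`, `log_likelihood`, `posterior`, and `cp1..cp(J-1)` interior
#'   change-point indices; the `segmentations` attribute holds the
#'   corresponding list of [segmentation] objects.
#' @export
top_segmentations <- function(series, J, N, cost = NULL) {
  T <- ncol(series$values)
  if (J < 1 || J > T) stop("J must satisfy 1 <= J <= T")
  if (N < 1) stop("N must be >= 1")
  if (is.null(cost)) cost <- cost_matrix(series)
  nb <- vector("list", J)        # nb[[j]][[t]]: scores desc + backpointers
  nb[[1]] <- lapply(seq_len(T), function(t)
    list(score = cost[1, t], u = 1L, k = 0L))
  if (J > 1) {
    for (j in 2:J) {
      nb[[j]] <- vector("list", T)
      for (t in j:T) {
        sc <- numeric(0); us <- integer(0); ks <- integer(0)
        for (u in j:t) {
          prev <- nb[[j - 1]][[u - 1L]]
          if (is.null(prev)) next
          sc <- c(sc, prev$score + cost[u, t])
          us <- c(us, rep(u, length(prev$score)))
          ks <- c(ks, seq_along(prev$score))
        }
        o <- order(-sc, us, ks)[seq_len(min(N, length(sc)))]
        nb[[j]][[t]] <- list(score = sc[o], u = us[o], k = ks[o])
      }
    }
  }
  top <- nb[[J]][[T]]
  n_out <- length(top$score)
  logM <- forward_logsums(cost, J)[J, T]
  segs <- vector("list", n_out)
  cps_mat <- matrix(NA_integer_, n_out, max(J - 1L, 0L))
  for (i in seq_len(n_out)) {
    cps <- integer(0)
    t <- T; j <- J; k <- i
    while (j >= 1) {
      cell <- nb[[j]][[t]]
      u <- cell$u[k]; kprev <- cell$k[k]
      if (j > 1) cps <- c(u, cps)
      t <- u - 1L; j <- j - 1L; k <- kprev
    }
    if (J > 1) cps_mat[i, ] <- cps
    segs[[i]] <- segmentation(cps, T, weeks = series$weeks)
  }
  out <- data.frame(rank = seq_len(n_out),
                    log_likelihood = top$score,
                    posterior = exp(top$score - logM))
  if (J > 1) {
    cps_df <- as.data.frame(cps_mat)
    names(cps_df) <- paste0("cp", seq_len(J - 1L))
    out <- cbind(out, cps_df)
  }
  attr(out, "segmentations") <- segs
  out
}

#' Posterior change-point and phase-occupancy profiles
#'
#' Exact smoothed posterior probabilities for a `J`-phase model:
#' `occupancy[t, j] = P(S_t = j | x; J)`, the probability of being in phase
#' `j` at time `t`, and `entry[t, j] = P(S_t = j, S_{t-1} = j - 1 | x; J)`,
#' the probability of entering phase `j` at time `t` (for `j = 1`, entry is
#' 1 at `t = 1`). Each occupancy row sums to 1 and each entry column for
#' `j >= 2` sums to 1; the entry profiles visualise change-point position
#' uncertainty.
#'
#' @inheritParams optimal_segmentation
#' @return list with `occupancy` and `entry`, both `T x J` matrices.
#' @export
posterior_profiles <- function(series, J, cost = NULL) {
  T <- ncol(series$values)
  if (J < 1 || J > T) stop("J must satisfy 1 <= J <= T")
  if (is.null(cost)) cost <- cost_matrix(series)
  q <- posterior_quantities(cost, J, profiles = TRUE)
  list(occupancy = q$occupancy, entry = q$entry)
}

#' Full per-J segmentation report
#'
#' Runs the whole model battery for `J = 1..Jmax` on one series: optimal
#' segmentation, log marginal likelihood, entropy, ICL, posterior of the
#' optimal segmentation, model posteriors, and optionally top-N lists and
#' posterior profiles.
#'
#' @inheritParams model_posteriors
#' @param top_n if `> 0`, include the top-N segmentations per `J`.
#' @param profiles include occupancy/entry profiles per `J`.
#' @return `segmentation_report` object: list with `per_J` (one entry per
#'   `J` holding `icl`, `log_marginal`, `entropy`, `d`, `optimal`
#'   (`phase_model`), `optimal_posterior`, and optionally `top`,
#'   `profiles`), plus `model_posteriors` and the ICL-preferred `icl_J`.
#' @export
segment_series <- function(series, Jmax = 6L, d = NULL,
                           penalty = c("logT", "logPT"),
                           top_n = 0L, profiles = FALSE) {
  penalty <- match.arg(penalty)
  T <- ncol(series$values)
  Jmax <- min(as.integer(Jmax), T)
  cost <- cost_matrix(series)
  C <- series$n_categories
  n_pen <- if (penalty == "logT") T else length(series$values)
  per_J <- vector("list", Jmax)
  half <- numeric(Jmax)
  for (J in seq_len(Jmax)) {
    q <- posterior_quantities(cost, J, profiles = profiles)
    dJ <- if (is.null(d)) (J - 1) + J * (C - 1) else d
    icl_J <- 2 * q$log_marginal - dJ * log(n_pen) - 2 * q$entropy
    opt <- optimal_segmentation(series, J, cost = cost)
    per_J[[J]] <- list(
      J = J, icl = icl_J, log_marginal = q$log_marginal,
      entropy = q$entropy, d = dJ, optimal = opt,
      optimal_posterior = exp(opt$log_likelihood - q$log_marginal))
    if (profiles)
      per_J[[J]]$profiles <- list(occupancy = q$occupancy, entry = q$entry)
    if (top_n > 0)
      per_J[[J]]$top <- top_segmentations(series, J, top_n, cost = cost)
    half[J] <- icl_J / 2
  }
  post <- exp(half - logsumexp(half))
  post <- post / sum(post)
  names(post) <- seq_len(Jmax)
  structure(list(genotype = series$genotype, per_J = per_J,
                 model_posteriors = post,
                 icl_J = which.max(vapply(per_J, `[[`, numeric(1), "icl"))),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> %s (ICL prefers J = %d)\n",
              if (is.null(x$genotype)) "" else x$genotype, x$icl_J))
  df <- data.frame(
    J = vapply(x$per_J, `[[`, numeric(1), "J"),
    ICL = round(vapply(x$per_J, `[[`, numeric(1), "icl"), 2),
    log_marginal = round(vapply(x$per_J, `[[`, numeric(1), "log_marginal"), 2),
    entropy = round(vapply(x$per_J, `[[`, numeric(1), "entropy"), 3),
    P_model = round(x$model_posteriors, 3),
    P_opt_seg = round(vapply(x$per_J, `[[`, numeric(1), "optimal_posterior"), 3))
  print(df, row.names = FALSE)
  invisible(x)
}
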