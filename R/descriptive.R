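#' Breadth-depth trade-off curve
#'
#' Per-capacity summary of the number of alternatives sampled: mean M,
#' standard error, the ratio mean(M)/C and the trial count.
#'
#' @param trials Trial tibble (needs `capacity` and `m`/`allocation`).
#' @return Tibble with columns `capacity`, `mean_m`, `sem`, `ratio`,
#'   `n_trials`.
#' @export
tradeoff_curve <- function(trials) {
  trials <- add_m(trials)
  dplyr::summarise(
    dplyr::group_by(trials, .data$capacity),
    mean_m = mean(.data$m),
    sem = stats::sd(.data$m) / sqrt(dplyr::n()),
    ratio = mean(.data$m) / .data$capacity[1],
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Fixed-intercept power-law fit of M against capacity
#'
#' Fits \eqn{M(C) = C^a} by zero-intercept least squares in log-log space
#' over trial-level points: \eqn{a = \sum \log C \log M / \sum (\log C)^2}.
#' This is the descriptive exponent used to summarise a sampling strategy
#' (1 = pure breadth, smaller = deeper).
#'
#' @param capacity Capacities (or a trial tibble as sole argument).
#' @param m Numbers of alternatives sampled, aligned with `capacity`.
#' @return List with `exponent`, `r2adj` (adjusted R-squared of the log-log
#'   regression through the origin) and `n`.
#' @examples
#' power_fit(2:10, 2:10)$exponent # 1: pure breadth
#' power_fit(c(2:10, 16, 32), c(2:10, 16, 32)^0.75)$exponent # 0.75
#' @export
power_fit <- function(capacity, m = NULL) {
  if (is.data.frame(capacity)) {
    capacity <- add_m(capacity)
    m <- capacity$m
    capacity <- capacity$capacity
  }
  stopifnot(length(capacity) == length(m), all(capacity >= 2), all(m >= 1))
  x <- log(capacity)
  y <- log(m)
  a <- sum(x * y) / sum(x * x)
  res <- y - a * x
  n <- length(y)
  # R^2 for a through-origin fit uses uncentred total sum of squares
  r2 <- if (sum(y^2) > 0) 1 - sum(res^2) / sum(y^2) else 1
  r2adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 1 - 1) else r2
  list(exponent = a, r2adj = r2adj, n = n)
}

#' Linear fit of M against capacity
#'
#' Ordinary least squares of \eqn{M(C) = aC + b}.
#'
#' @inheritParams power_fit
#' @return List with `a` (slope), `b` (intercept), `r2adj`, `n`.
#' @export
linear_fit <- function(capacity, m = NULL) {
  if (is.data.frame(capacity)) {
    capacity <- add_m(capacity)
    m <- capacity$m
    capacity <- capacity$capacity
  }
  if (length(unique(capacity)) < 3L) {
    stop("linear fit needs at least 3 distinct capacities", call. = FALSE)
  }
  fit <- stats::lm(m ~ capacity)
  s <- summary(fit)
  list(
    a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
    r2adj = s$adj.r.squared, n = length(m)
  )
}

#' Piecewise power-law fit with a free breakpoint
#'
#' Fits \eqn{M(C) = C^{a_1}} for \eqn{C \le B} and \eqn{M(C) = C^{a_2} + b}
#' for \eqn{C > B}, for every candidate breakpoint in `breakpoint_grid`,
#' keeping the breakpoint with the smallest residual sum of squares. The
#' lower branch is fitted as a zero-intercept log-log regression; the upper
#' branch by profiling b out (for fixed \eqn{a_2} the optimal b is the mean
#' residual) and optimising \eqn{a_2} numerically.
#'
#' @inheritParams power_fit
#' @param breakpoint_grid Candidate breakpoints B (default 3..9, the
#'   narrow-design grid; use 3..16 for wide designs).
#' @return List with `a1`, `a2`, `b`, `breakpoint`, `r2adj`, `n`.
#' @export
piecewise_power_fit <- function(capacity, m = NULL, breakpoint_grid = 3:9) {
  if (is.data.frame(capacity)) {
    capacity <- add_m(capacity)
    m <- capacity$m
    capacity <- capacity$capacity
  }
  best <- NULL
  for (B in breakpoint_grid) {
    lo <- capacity <= B
    if (sum(lo) < 2L || sum(!lo) < 2L) next
    a1 <- sum(log(capacity[lo]) * log(m[lo])) / sum(log(capacity[lo])^2)
    rss_lo <- sum((m[lo] - capacity[lo]^a1)^2)
    up_c <- capacity[!lo]
    up_m <- m[!lo]
    rss_up_fn <- function(a2) {
      b <- mean(up_m - up_c^a2)
      sum((up_m - up_c^a2 - b)^2)
    }
    opt <- stats::optimize(rss_up_fn, interval = c(0, 1.5))
    a2 <- opt$minimum
    b <- mean(up_m - up_c^a2)
    rss <- rss_lo + opt$objective
    if (is.null(best) || rss < best$rss) {
      best <- list(a1 = a1, a2 = a2, b = b, breakpoint = B, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("no breakpoint leaves at least 2 capacities on each side", call. = FALSE)
  }
  n <- length(m)
  tss <- sum((m - mean(m))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else 1
  k <- 4 # a1, a2, b, B
  r2adj <- if (n > k + 1) 1 - (1 - r2) * (n - 1) / (n - k - 1) else r2
  list(
    a1 = best$a1, a2 = best$a2, b = best$b, breakpoint = best$breakpoint,
    r2adj = r2adj, n = n
  )
}

#' Per-capacity deviation of observed from optimal breadth
#'
#' The difference \eqn{M_{opt}(C) - M} per trial, summarised per capacity
#' and environment. Positive values mean the observed allocation was deeper
#' (fewer alternatives) than optimal.
#'
#' @param trials Trial tibble.
#' @param optimal_curves An [optimal_curve()] tibble or named list by
#'   environment.
#' @return Tibble with `environment`, `capacity`, `mean_diff`, `sem`,
#'   `n_trials`.
#' @export
deviation_from_optimal <- function(trials, optimal_curves) {
  trials <- join_optimal_m(add_m(trials), optimal_curves)
  dplyr::summarise(
    dplyr::group_by(trials, .data$environment, .data$capacity),
    mean_diff = mean(.data$m_opt - .data$m),
    sem = stats::sd(.data$m_opt - .data$m) / sqrt(dplyr::n()),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Standard deviation of a sample allocation
#'
#' The sample standard deviation (n - 1 denominator) of the per-alternative
#' sample counts; a measure of allocation (in)homogeneity. A single-part
#' allocation returns 0 by convention.
#'
#' @param counts Positive integer counts per sampled alternative.
#' @return Non-negative scalar.
#' @examples
#' allocation_sd(c(2, 2)) # 0
#' allocation_sd(c(2, 1, 1)) # 0.577
#' allocation_sd(c(1, 3)) # 1.414
#' @export
allocation_sd <- function(counts) {
  stopifnot(length(counts) >= 1L, all(counts >= 1))
  if (length(counts) == 1L) {
    return(0)
  }
  stats::sd(counts)
}

#' Allocation homogeneity relative to the ideal observer
#'
#' Over trials where the optimal allocation is not pure breadth
#' (\eqn{M_{opt} < C}), the mean difference between the standard deviation
#' of the observed sample counts and that of the optimal partition at the
#' same capacity and environment. Negative values indicate more homogeneous
#' sampling than optimal.
#'
#' @inheritParams deviation_from_optimal
#' @return Tibble per participant and environment with `mean_sd_diff` and
#'   `n_trials`; trials with \eqn{M_{opt} = C} are excluded, and a
#'   participant-environment block with no qualifying trials is dropped.
#' @export
homogeneity_vs_optimal <- function(trials, optimal_curves) {
  trials <- join_optimal_m(add_m(trials), optimal_curves)
  trials <- trials[trials$m_opt < trials$capacity, , drop = FALSE]
  if (nrow(trials) == 0L) {
    warning("no trials with M_opt < C; empty result", call. = FALSE)
    return(tibble::tibble(
      participant_id = character(), environment = character(),
      mean_sd_diff = numeric(), n_trials = integer()
    ))
  }
  curve <- if (is.data.frame(optimal_curves)) {
    optimal_curves
  } else {
    dplyr::bind_rows(optimal_curves)
  }
  key <- paste(curve$environment, curve$capacity)
  opt_sd <- vapply(curve$partition, allocation_sd, numeric(1))
  names(opt_sd) <- key
  trials$obs_sd <- vapply(trials$allocation,
    function(a) allocation_sd(allocation_counts(a)), numeric(1)
  )
  trials$opt_sd <- opt_sd[paste(trials$environment, trials$capacity)]
  dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$environment),
    mean_sd_diff = mean(.data$obs_sd - .data$opt_sd),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Outcome shortfall relative to the ideal observer
#'
#' Over the same trial set as [homogeneity_vs_optimal()] (\eqn{M_{opt} < C}),
#' the mean observed reward minus the ideal observer's expected reward (per
#' 100 purchased units) at the same capacity and environment.
#'
#' @inheritParams deviation_from_optimal
#' @return Tibble per participant and environment with `mean_outcome_diff`
#'   (percentage points of the 100-unit purchase) and `n_trials`.
#' @export
outcome_vs_optimal <- function(trials, optimal_curves) {
  trials <- join_optimal_m(add_m(trials), optimal_curves)
  trials <- trials[trials$m_opt < trials$capacity, , drop = FALSE]
  curve <- if (is.data.frame(optimal_curves)) {
    optimal_curves
  } else {
    dplyr::bind_rows(optimal_curves)
  }
  opt_rew <- curve$expected_reward
  names(opt_rew) <- paste(curve$environment, curve$capacity)
  trials$opt_reward <- opt_rew[paste(trials$environment, trials$capacity)]
  dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$environment),
    mean_outcome_diff = mean(.data$reward - .data$opt_reward),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Classify the order of a sample-allocation sequence
#'
#' Trials with M = 1 (pure depth) or M = C (pure breadth) are `excluded`.
#' A sequence is `depth_focused` when every alternative's samples are
#' contiguous (each alternative is finished before the next is started),
#' `breadth_focused` when the first M samples go to M distinct alternatives
#' (everything is touched once before any repeat), and `mixed` otherwise.
#' A sequence passing both tests is labelled `depth_focused`.
#'
#' @param sequence Integer allocation sequence (one alternative index per
#'   sample, in order).
#' @return One of `"depth_focused"`, `"breadth_focused"`, `"mixed"`,
#'   `"excluded"`.
#' @examples
#' classify_sequence(c(1, 1, 2, 3, 3, 4, 4)) # depth_focused
#' classify_sequence(c(1, 2, 3, 4, 4, 1, 3)) # breadth_focused
#' classify_sequence(c(1, 2, 1, 2, 3)) # mixed
#' @export
classify_sequence <- function(sequence) {
  m <- allocation_m(sequence)
  capacity <- length(sequence)
  if (m == 1L || m == capacity) {
    return("excluded")
  }
  runs <- rle(sequence)$values
  if (!anyDuplicated(runs)) {
    return("depth_focused")
  }
  if (!anyDuplicated(sequence[seq_len(m)])) {
    return("breadth_focused")
  }
  "mixed"
}

#' Fractions of depth- and breadth-focused sequences per (M, C) cell
#'
#' Classifies every eligible trial (1 < M < C) and reports, per combination
#' of M and capacity, the fraction following each sequence strategy. Cells
#' with fewer than `min_trials` trials (pooled over participants) are
#' suppressed, mirroring the display rule of the original analysis.
#'
#' @param trials Trial tibble.
#' @param min_trials Minimum trials per (M, C) cell (default 10).
#' @return Tibble with `m`, `capacity`, `n_trials` and fractions
#'   `depth_focused`, `breadth_focused`, `mixed` (summing to 1 per cell).
#' @export
strategy_fractions <- function(trials, min_trials = 10L) {
  trials <- add_m(trials)
  trials$strategy <- vapply(trials$allocation, classify_sequence, character(1))
  trials <- trials[trials$strategy != "excluded", , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(trials, .data$m, .data$capacity),
    n_trials = dplyr::n(),
    depth_focused = mean(.data$strategy == "depth_focused"),
    breadth_focused = mean(.data$strategy == "breadth_focused"),
    mixed = mean(.data$strategy == "mixed"),
    .groups = "drop"
  )
  out[out$n_trials >= min_trials, , drop = FALSE]
}

#' Resampling of the previously chosen alternative
#'
#' For consecutive trial pairs within a block, computes per participant and
#' previous-reward level (median split within capacity x environment, ties
#' to the low bin): the probability that the previously chosen alternative
#' receives at least one sample on the next trial, and the mean fraction of
#' the next trial's capacity allocated to it.
#'
#' @param trials Trial tibble with `participant_id`, `environment`, `block`,
#'   `trial`, `capacity`, `allocation`, `chosen_supplier`, `reward`.
#' @return Tibble per participant x previous-reward level (`prev_reward`:
#'   `"low"`/`"high"`) with `p_resample`, `frac_capacity`, `n_pairs`.
#' @export
resampling_stats <- function(trials) {
  trials <- add_m(trials)
  trials <- dplyr::arrange(trials, .data$participant_id, .data$block, .data$trial)
  trials <- dplyr::group_by(trials, .data$participant_id, .data$capacity,
    .data$environment
  )
  trials <- dplyr::mutate(trials,
    reward_level = ifelse(.data$reward <= stats::median(.data$reward),
      "low", "high"
    )
  )
  trials <- dplyr::ungroup(trials)
  trials <- dplyr::group_by(trials, .data$participant_id, .data$block)
  trials <- dplyr::mutate(trials,
    prev_chosen = dplyr::lag(.data$chosen_supplier),
    prev_reward = dplyr::lag(.data$reward_level)
  )
  trials <- dplyr::ungroup(trials)
  pairs <- trials[!is.na(trials$prev_chosen), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(
      participant_id = character(), prev_reward = character(),
      p_resample = numeric(), frac_capacity = numeric(), n_pairs = integer()
    ))
  }
  pairs$n_to_prev <- mapply(
    function(a, s) sum(a == s), pairs$allocation, pairs$prev_chosen
  )
  dplyr::summarise(
    dplyr::group_by(pairs, .data$participant_id, .data$prev_reward),
    p_resample = mean(.data$n_to_prev > 0),
    frac_capacity = mean(.data$n_to_prev / .data$capacity),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
}

#' Agreement of final choices with the normative and proportional rules
#'
#' Per participant: the fraction of trials whose chosen alternative lies in
#' the argmax set of the normative value \eqn{V^{norm}} and of the
#' proportional value \eqn{V^{prop}}. On trials disagreeing with
#' \eqn{V^{prop}}, also the mean difference in sample counts between the
#' chosen alternative and the \eqn{V^{prop}}-best one (the argmax member
#' with the most samples, when tied).
#'
#' @param trials Trial tibble.
#' @return Tibble per participant with `frac_norm`, `frac_prop`,
#'   `n_disagree_prop`, `mean_extra_samples` (NA when no disagreements).
#' @export
choice_agreement <- function(trials) {
  trials <- add_m(trials)
  per_trial <- purrr::pmap(
    list(trials$allocation, trials$outcomes, trials$chosen_supplier,
      trials$environment
    ),
    function(alloc, outc, chosen, env_label) {
      norm_set <- normative_choice(alloc, outc, env_label)
      prop_set <- proportional_choice(alloc, outc)
      agree_prop <- chosen %in% prop_set
      extra <- NA_real_
      if (!agree_prop) {
        counts <- allocation_counts(alloc)
        best_prop <- prop_set[which.max(counts[as.character(prop_set)])]
        extra <- counts[[as.character(chosen)]] - counts[[as.character(best_prop)]]
      }
      c(
        agree_norm = chosen %in% norm_set, agree_prop = agree_prop,
        extra = extra
      )
    }
  )
  res <- do.call(rbind, per_trial)
  trials$agree_norm <- res[, "agree_norm"]
  trials$agree_prop <- res[, "agree_prop"]
  trials$extra <- res[, "extra"]
  dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id),
    frac_norm = mean(.data$agree_norm),
    frac_prop = mean(.data$agree_prop),
    n_disagree_prop = sum(!.data$agree_prop),
    mean_extra_samples = if (any(!.data$agree_prop)) {
      mean(.data$extra[!.data$agree_prop])
    } else {
      NA_real_
    },
    .groups = "drop"
  )
}
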