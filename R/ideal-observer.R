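#' Beta-Binomial probability mass function
#'
#' Probability of observing `k` good samples out of `n` drawn from an
#' alternative whose quality p is itself drawn from the environment's
#' Beta(\eqn{\alpha}, \eqn{\beta}) prior:
#' \deqn{P(K = k) = \binom{n}{k} B(k + \alpha, n - k + \beta) / B(\alpha, \beta).}
#'
#' @param k Number of successes (vectorised), each in \[0, n\].
#' @param n Number of samples.
#' @param env Environment label or `bd_environment`.
#' @return Probabilities, same length as `k`.
#' @examples
#' beta_binomial_pmf(1, 1, "poor") # prior mean, 0.25
#' sum(beta_binomial_pmf(0:5, 5, "rich")) # 1
#' @export
beta_binomial_pmf <- function(k, n, env) {
  env <- bd_environment(env)
  if (any(k < 0L) || any(k > n)) {
    stop("k must lie in [0, n]", call. = FALSE)
  }
  exp(lchoose(n, k) + lbeta(k + env$alpha, n - k + env$beta) -
    lbeta(env$alpha, env$beta))
}

#' Posterior-mean value of a sampled alternative
#'
#' Under the conjugate Beta prior, the posterior mean quality after observing
#' `k` good samples out of `n` is \eqn{(k + \alpha) / (n + \alpha + \beta)}.
#' With `n = 0` this is the prior mean. This is the normative value
#' \eqn{V^{norm}} used for the final choice.
#'
#' @inheritParams beta_binomial_pmf
#' @return Posterior mean(s) in (0, 1).
#' @examples
#' posterior_mean(1, 1, "neutral") # 4/7
#' posterior_mean(0, 0, "poor") # 0.25
#' @export
posterior_mean <- function(k, n, env) {
  env <- bd_environment(env)
  if (any(k < 0L) || any(k > n)) {
    stop("k must lie in [0, n]", call. = FALSE)
  }
  (k + env$alpha) / (n + env$alpha + env$beta)
}

#' Distribution of the posterior-mean value after n samples
#'
#' The posterior mean of an alternative after `n` samples takes the values
#' \eqn{(k + \alpha)/(n + \alpha + \beta)}, k = 0..n, with Beta-Binomial
#' probabilities.
#'
#' @inheritParams beta_binomial_pmf
#' @return List with strictly increasing `support` and matching `probs`
#'   (summing to 1).
#' @export
value_distribution <- function(n, env) {
  env <- bd_environment(env)
  list(
    support = posterior_mean(0:n, n, env),
    probs = beta_binomial_pmf(0:n, n, env)
  )
}

# Support values rounded to a fixed grid so numerically coincident values
# from different parts merge before the CDF product.
.round_support <- function(x) round(x, 12)

#' Exact expected maximum posterior-mean value of a sample partition
#'
#' For a partition \eqn{\{n_1, \dots, n_m\}} of the capacity, each part's
#' posterior mean is an independent Beta-Binomial-mixed discrete variable;
#' the expected reward of the allocation (per purchased unit) is the expected
#' maximum over parts. Computed exactly via the product of the parts' CDFs on
#' the merged support: \eqn{P(\max \le v) = \prod_i F_i(v)}.
#'
#' @param partition Positive integers, the samples given to each sampled
#'   alternative (order irrelevant).
#' @param env Environment label or `bd_environment`.
#' @return The expected maximum posterior mean, a value in (0, 1).
#' @examples
#' expected_max_value(c(1, 1), "neutral") # 15/28
#' expected_max_value(7, "rich") # martingale: prior mean 0.75
#' @export
expected_max_value <- function(partition, env) {
  env <- bd_environment(env)
  if (length(partition) == 0L) stop("partition must be non-empty", call. = FALSE)
  if (any(partition < 1L)) stop("partition parts must be positive", call. = FALSE)
  sizes <- table(partition)
  ns <- as.integer(names(sizes))
  vals <- lapply(ns, function(n) .round_support(posterior_mean(0:n, n, env)))
  pmfs <- lapply(ns, function(n) beta_binomial_pmf(0:n, n, env))
  grid <- sort(unique(unlist(vals)))
  cdf <- rep(1, length(grid))
  for (i in seq_along(ns)) {
    f_i <- c(0, cumsum(pmfs[[i]]))[findInterval(grid, vals[[i]]) + 1L]
    cdf <- cdf * f_i^as.integer(sizes[[i]])
  }
  sum(grid * diff(c(0, cdf)))
}

#' Enumerate integer partitions
#'
#' All partitions of `capacity` with at most `max_parts` parts, each exactly
#' once, parts non-increasing, in descending lexicographic order (so `{C}`
#' first, `{1, 1, ..., 1}` last).
#'
#' @param capacity Positive integer to partition.
#' @param max_parts Maximum number of parts (e.g. the number of available
#'   alternatives).
#' @return List of integer vectors.
#' @examples
#' enumerate_partitions(4, 4) # {4} {3,1} {2,2} {2,1,1} {1,1,1,1}
#' length(enumerate_partitions(32, 32)) # 8349
#' @export
enumerate_partitions <- function(capacity, max_parts) {
  stopifnot(capacity >= 1L, max_parts >= 1L)
  out <- vector("list", 0L)
  n_out <- 0L
  rec <- function(remaining, max_part, parts_left, acc) {
    if (remaining == 0L) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- acc
      return(invisible())
    }
    if (parts_left == 0L) {
      return(invisible())
    }
    # a feasibility cut: parts_left parts of size <= max_part must cover remaining
    if (remaining > parts_left * max_part) {
      return(invisible())
    }
    for (p in min(remaining, max_part):1L) {
      rec(remaining - p, p, parts_left - 1L, c(acc, p))
    }
  }
  rec(as.integer(capacity), as.integer(capacity), as.integer(max_parts), integer(0))
  out[seq_len(n_out)]
}

#' Optimal allocation of a sampling budget
#'
#' Searches every partition of the capacity into at most `max_parts` parts
#' for the one maximising [expected_max_value()]. Ties within `tol` are
#' broken deterministically: fewer parts first, then the lexicographically
#' largest non-increasing partition.
#'
#' @param capacity Sampling budget (>= 2).
#' @param env Environment label or `bd_environment`.
#' @param max_parts Number of available alternatives.
#' @param tol Tie tolerance on expected value.
#' @return A list with `capacity`, `best_partition`, `m_opt` (number of
#'   parts), `expected_value` and `expected_reward` (per 100 purchased units).
#' @examples
#' optimal_allocation(4, "poor", 10)$m_opt # 4: pure breadth at low capacity
#' @export
optimal_allocation <- function(capacity, env, max_parts, tol = 1e-12) {
  env <- bd_environment(env)
  stopifnot(capacity >= 2L, max_parts >= 1L)
  parts <- enumerate_partitions(capacity, max_parts)
  # precompute per part-size support/pmf once; partitions reuse them heavily
  vals <- lapply(1:capacity, function(n) .round_support(posterior_mean(0:n, n, env)))
  cums <- lapply(1:capacity, function(n) c(0, cumsum(beta_binomial_pmf(0:n, n, env))))
  ev <- vapply(parts, function(pt) {
    sizes <- table(pt)
    ns <- as.integer(names(sizes))
    grid <- sort(unique(unlist(vals[ns])))
    cdf <- rep(1, length(grid))
    for (i in seq_along(ns)) {
      f_i <- cums[[ns[i]]][findInterval(grid, vals[[ns[i]]]) + 1L]
      cdf <- cdf * f_i^as.integer(sizes[[i]])
    }
    sum(grid * diff(c(0, cdf)))
  }, numeric(1))
  cand <- which(ev >= max(ev) - tol)
  n_parts <- lengths(parts[cand])
  cand <- cand[n_parts == min(n_parts)]
  # enumeration order is descending lexicographic; the first candidate is
  # the lexicographically largest partition
  best <- cand[1L]
  list(
    capacity = as.integer(capacity),
    best_partition = parts[[best]],
    m_opt = length(parts[[best]]),
    expected_value = ev[best],
    expected_reward = 100 * ev[best]
  )
}

#' Optimal breadth-depth trade-off curve
#'
#' Maps [optimal_allocation()] over a set of capacities.
#'
#' @param env Environment label or `bd_environment`.
#' @param capacities Integer capacities.
#' @param max_parts Number of available alternatives.
#' @return A tibble with columns `environment`, `capacity`, `m_opt`,
#'   `expected_value`, `expected_reward` and a `partition` list-column.
#' @examples
#' optimal_curve("poor", 2:6, 10)
#' @export
optimal_curve <- function(env, capacities, max_parts) {
  env <- bd_environment(env)
  rows <- lapply(capacities, optimal_allocation, env = env, max_parts = max_parts)
  tibble::tibble(
    environment = env$label,
    capacity = vapply(rows, `[[`, integer(1), "capacity"),
    m_opt = vapply(rows, `[[`, integer(1), "m_opt"),
    expected_value = vapply(rows, `[[`, numeric(1), "expected_value"),
    expected_reward = vapply(rows, `[[`, numeric(1), "expected_reward"),
    partition = lapply(rows, `[[`, "best_partition")
  )
}

#' Monte-Carlo estimate of a partition's expected maximum value
#'
#' Simulation cross-check for [expected_max_value()]: draws qualities from
#' the prior, binomial outcomes per part, and averages the maximum posterior
#' mean.
#'
#' @inheritParams expected_max_value
#' @param n_sims Number of simulated trials.
#' @param seed Optional seed (applied locally; the global RNG is untouched).
#' @return List with `estimate` and `se` (standard error).
#' @examples
#' monte_carlo_expected_value(c(1, 1), "neutral", n_sims = 1e4, seed = 1)
#' @export
monte_carlo_expected_value <- function(partition, env, n_sims = 1e5, seed = NULL) {
  env <- bd_environment(env)
  stopifnot(n_sims >= 1L, length(partition) >= 1L, all(partition >= 1L))
  if (!is.null(seed)) withr::local_seed(seed)
  m <- length(partition)
  # column = one simulated trial; partition recycles down columns
  p <- matrix(stats::rbeta(m * n_sims, env$alpha, env$beta), nrow = m)
  k <- matrix(stats::rbinom(m * n_sims, partition, p), nrow = m)
  vals <- (k + env$alpha) / (partition + env$alpha + env$beta)
  best <- Reduce(pmax, lapply(seq_len(m), function(i) vals[i, ]))
  list(estimate = mean(best), se = stats::sd(best) / sqrt(n_sims))
}

#' Final-choice rules over sampled alternatives
#'
#' `normative_choice()` returns the sampled alternative(s) maximising the
#' posterior-mean value \eqn{V^{norm}_i = (\sum_s O_{s,i} + \alpha) /
#' (N_i + \alpha + \beta)}; `proportional_choice()` maximises the prior-free
#' proportion of good samples \eqn{V^{prop}_i = \sum_s O_{s,i} / N_i}. Both
#' return the full argmax set (ties included). Unsampled alternatives are
#' never choosable.
#'
#' @param allocation Integer vector of alternative indices, one per sample.
#' @param outcomes 0/1 vector aligned with `allocation`.
#' @param env Environment label or `bd_environment` (normative rule only).
#' @return Integer vector of alternative indices (the argmax set).
#' @examples
#' # poor environment: 3-of-4 beats 1-of-1 normatively, loses proportionally
#' alloc <- c(1, 1, 1, 1, 2)
#' outc <- c(1, 1, 1, 0, 1)
#' normative_choice(alloc, outc, "poor") # 1
#' proportional_choice(alloc, outc) # 2
#' @export
normative_choice <- function(allocation, outcomes, env) {
  env <- bd_environment(env)
  vals <- .per_supplier_kn(allocation, outcomes)
  v <- (vals$k + env$alpha) / (vals$n + env$alpha + env$beta)
  vals$supplier[v >= max(v) - 1e-12]
}

#' @rdname normative_choice
#' @export
proportional_choice <- function(allocation, outcomes) {
  vals <- .per_supplier_kn(allocation, outcomes)
  v <- vals$k / vals$n
  vals$supplier[v >= max(v) - 1e-12]
}

.per_supplier_kn <- function(allocation, outcomes) {
  stopifnot(length(allocation) == length(outcomes), length(allocation) >= 1L)
  sup <- sort(unique(allocation))
  k <- vapply(sup, function(s) sum(outcomes[allocation == s]), numeric(1))
  n <- vapply(sup, function(s) sum(allocation == s), numeric(1))
  list(supplier = as.integer(sup), k = k, n = n)
}
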