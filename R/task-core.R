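#' Draw alternative qualities from the environment prior
#'
#' Each alternative's success probability \eqn{p_i} is an independent draw
#' from the environment's Beta(\eqn{\alpha}, \eqn{\beta}) prior; qualities are
#' redrawn independently on every trial.
#'
#' @param env Environment label or `bd_environment`.
#' @param n_suppliers Number of alternatives to draw for.
#' @return Numeric vector of `n_suppliers` probabilities in \[0, 1\].
#' @examples
#' set.seed(1)
#' draw_supplier_qualities("neutral", 5)
#' @export
draw_supplier_qualities <- function(env, n_suppliers) {
  env <- bd_environment(env)
  if (n_suppliers < 1L) stop("n_suppliers must be >= 1", call. = FALSE)
  stats::rbeta(n_suppliers, env$alpha, env$beta)
}

#' Summarise a sample-allocation sequence
#'
#' An allocation is the ordered sequence of alternative indices that received
#' the trial's samples, one index per sample. `allocation_counts()` returns
#' the per-alternative sample counts \eqn{n_i} (named by alternative index);
#' `allocation_m()` returns the number of distinct alternatives sampled, M.
#'
#' @param sequence Integer vector of alternative indices (1-based), length =
#'   capacity, in allocation order.
#' @return `allocation_counts()`: named integer vector of counts;
#'   `allocation_m()`: integer M.
#' @examples
#' allocation_counts(c(2, 2, 5, 7)) # n = {2, 1, 1}
#' allocation_m(c(2, 2, 5, 7)) # M = 3
#' @export
allocation_counts <- function(sequence) {
  stopifnot(length(sequence) >= 1L, all(sequence >= 1L))
  tab <- table(factor(sequence))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @rdname allocation_counts
#' @export
allocation_m <- function(sequence) {
  length(unique(sequence))
}

check_allocation <- function(sequence, capacity, n_suppliers) {
  if (length(sequence) != capacity) {
    stop("allocation length (", length(sequence), ") != capacity (", capacity, ")",
      call. = FALSE
    )
  }
  if (any(sequence < 1L) || any(sequence > n_suppliers)) {
    stop("allocation indices must lie in [1, ", n_suppliers, "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate one trial of the sampling task
#'
#' Given an allocation, draws per-sample Bernoulli(\eqn{p_i}) outcomes for the
#' alternative that receives each sample (so the total outcome at alternative
#' i is Binomial(\eqn{n_i}, \eqn{p_i})), applies a choice rule restricted to
#' the sampled alternatives, and draws the final reward as the number of good
#' units in a bulk purchase of 100 from the chosen alternative,
#' Binomial(100, \eqn{p_{chosen}}).
#'
#' @param env Environment label or `bd_environment`.
#' @param capacity Number of samples available this trial.
#' @param allocation Integer vector of alternative indices, length `capacity`.
#' @param choice_rule Function `(allocation, outcomes)` returning the chosen
#'   alternative index; must return a sampled alternative. Defaults to the
#'   normative rule with random tie-breaking.
#' @param n_suppliers Number of available alternatives.
#' @param truth_p Optional fixed vector of per-alternative success
#'   probabilities (length `n_suppliers`); drawn from the prior when `NULL`.
#' @param purchase_size Units bought from the chosen alternative (default 100).
#' @return A list with `capacity`, `allocation`, `outcomes` (0/1 per sample),
#'   `chosen_supplier`, `reward` and `truth_p`.
#' @examples
#' set.seed(1)
#' simulate_trial("neutral", 4, c(1, 1, 2, 3), n_suppliers = 10)
#' @export
simulate_trial <- function(env, capacity, allocation, choice_rule = NULL,
                           n_suppliers, truth_p = NULL, purchase_size = 100L) {
  env <- bd_environment(env)
  check_allocation(allocation, capacity, n_suppliers)
  if (is.null(truth_p)) {
    truth_p <- draw_supplier_qualities(env, n_suppliers)
  } else {
    stopifnot(length(truth_p) == n_suppliers, all(truth_p >= 0), all(truth_p <= 1))
  }
  outcomes <- stats::rbinom(capacity, 1L, truth_p[allocation])
  if (is.null(choice_rule)) {
    choice_rule <- function(allocation, outcomes) {
      best <- normative_choice(allocation, outcomes, env)
      if (length(best) > 1L) best <- sample(best, 1L)
      best
    }
  }
  chosen <- as.integer(choice_rule(allocation, outcomes))
  if (length(chosen) != 1L || !(chosen %in% allocation)) {
    stop("choice rule must return a single sampled alternative", call. = FALSE)
  }
  reward <- stats::rbinom(1L, purchase_size, truth_p[chosen])
  list(
    capacity = as.integer(capacity),
    allocation = as.integer(allocation),
    outcomes = as.integer(outcomes),
    chosen_supplier = chosen,
    reward = as.integer(reward),
    truth_p = truth_p
  )
}
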