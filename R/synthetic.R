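#' Specification of a simulated participant
#'
#' A synthetic agent samples M alternatives per trial with mean
#' \eqn{M(C) = C^w} corrupted by binomial or Gaussian noise, splits the
#' capacity over them by a split rule, orders the samples by a sequence
#' rule, and picks the final alternative by the normative or proportional
#' value with an occasional uniform lapse.
#'
#' @param w Power-law exponent of the breadth-depth trade-off (> 0).
#' @param noise `list(kind = "binomial", p = ...)` or
#'   `list(kind = "gaussian", a = ..., b = ...)` with s.d. \eqn{a + bC}.
#' @param split_rule How capacity is divided over the M alternatives:
#'   `"homogeneous"` (parts differ by at most 1), `"optimal_partition"`
#'   (the value-maximising partition with M parts), or
#'   `"random_composition"` (uniform composition).
#' @param sequence_rule Allocation order: `"depth_focused"`,
#'   `"breadth_focused"` or `"interleaved_random"`.
#' @param choice_rule `"v_norm"` or `"v_prop"`.
#' @param lapse Probability of choosing uniformly among sampled
#'   alternatives instead of by the choice rule.
#' @param resample_bias Probability of forcing the previously chosen
#'   alternative into the sampled set after a high previous reward
#'   (above the environment's chance level); 0 disables history effects.
#' @return An `bd_agent` list.
#' @export
agent_spec <- function(w = 0.75,
                       noise = list(kind = "binomial", p = 0.9),
                       split_rule = c("homogeneous", "optimal_partition",
                         "random_composition"
                       ),
                       sequence_rule = c("depth_focused", "breadth_focused",
                         "interleaved_random"
                       ),
                       choice_rule = c("v_norm", "v_prop"),
                       lapse = 0, resample_bias = 0) {
  stopifnot(w > 0, lapse >= 0, lapse <= 1, resample_bias >= 0, resample_bias <= 1)
  if (noise$kind == "binomial") {
    stopifnot(noise$p > 0, noise$p <= 1)
  } else if (noise$kind == "gaussian") {
    stopifnot(is.numeric(noise$a), is.numeric(noise$b))
  } else {
    stop("noise kind must be 'binomial' or 'gaussian'", call. = FALSE)
  }
  structure(
    list(
      w = w, noise = noise, split_rule = match.arg(split_rule),
      sequence_rule = match.arg(sequence_rule),
      choice_rule = match.arg(choice_rule),
      lapse = lapse, resample_bias = resample_bias
    ),
    class = "bd_agent"
  )
}

#' Draw the number of alternatives an agent samples
#'
#' A noisy draw around \eqn{C^w}: binomial noise draws
#' M ~ Binomial(round(C^w / p), p); Gaussian noise rounds
#' \eqn{C^w + N(0, a + bC)}. The draw is clamped to
#' \[1, min(C, n_suppliers)\].
#'
#' @param agent An [agent_spec()].
#' @param capacity Trial capacity.
#' @param n_suppliers Available alternatives.
#' @return List with integer `m` and logical `clamped`.
#' @export
draw_m <- function(agent, capacity, n_suppliers) {
  target <- capacity^agent$w
  raw <- if (agent$noise$kind == "binomial") {
    n <- max(1L, as.integer(round(target / agent$noise$p)))
    stats::rbinom(1L, n, agent$noise$p)
  } else {
    sig <- agent$noise$a + agent$noise$b * capacity
    round(target + stats::rnorm(1L, 0, max(sig, 1e-9)))
  }
  m <- min(max(raw, 1L), min(capacity, n_suppliers))
  list(m = as.integer(m), clamped = m != raw)
}

.split_counts <- function(m, capacity, split_rule, env = NULL) {
  if (m == capacity) {
    return(rep(1L, m))
  }
  switch(split_rule,
    homogeneous = {
      base <- capacity %/% m
      extra <- capacity %% m
      base + (seq_len(m) <= extra)
    },
    optimal_partition = {
      if (is.null(env)) stop("optimal_partition split needs `env`", call. = FALSE)
      parts <- enumerate_partitions(capacity, m)
      parts <- parts[lengths(parts) == m]
      ev <- vapply(parts, expected_max_value, numeric(1), env = env)
      parts[[which.max(ev)]]
    },
    random_composition = {
      cuts <- sort(sample.int(capacity - 1L, m - 1L))
      diff(c(0L, cuts, capacity))
    },
    stop("unknown split rule: ", split_rule, call. = FALSE)
  )
}

#' Build an agent's sample allocation for one trial
#'
#' Picks M distinct alternatives (optionally forcing in the previously
#' chosen one), splits the capacity over them per the split rule, and
#' orders the samples per the sequence rule.
#'
#' @param m Number of alternatives to sample (1 <= m <= min(C, suppliers)).
#' @param capacity Trial capacity.
#' @param n_suppliers Available alternatives.
#' @param split_rule,sequence_rule See [agent_spec()].
#' @param env Environment (needed for `"optimal_partition"`).
#' @param force_include Optional alternative index guaranteed a sample.
#' @return Integer allocation sequence of length `capacity`.
#' @export
allocate_samples <- function(m, capacity, n_suppliers,
                             split_rule = "homogeneous",
                             sequence_rule = "depth_focused",
                             env = NULL, force_include = NULL) {
  if (m < 1L || m > min(capacity, n_suppliers)) {
    stop("infeasible M: must lie in [1, min(capacity, n_suppliers)]",
      call. = FALSE
    )
  }
  ids <- sample.int(n_suppliers, m)
  if (!is.null(force_include) && !(force_include %in% ids)) {
    ids[sample.int(m, 1L)] <- as.integer(force_include)
  }
  shuffle <- function(x) x[sample.int(length(x))] # length-safe sample()
  counts <- shuffle(.split_counts(m, capacity, split_rule, env = env))
  switch(sequence_rule,
    depth_focused = rep(ids, counts),
    breadth_focused = c(ids, shuffle(rep(ids, counts - 1L))),
    interleaved_random = shuffle(rep(ids, counts)),
    stop("unknown sequence rule: ", sequence_rule, call. = FALSE)
  )
}

.agent_choice <- function(agent, allocation, outcomes, env) {
  sampled <- unique(allocation)
  if (agent$lapse > 0 && stats::runif(1L) < agent$lapse) {
    return(sampled[sample.int(length(sampled), 1L)])
  }
  best <- if (agent$choice_rule == "v_norm") {
    normative_choice(allocation, outcomes, env)
  } else {
    proportional_choice(allocation, outcomes)
  }
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}

#' Generate a synthetic trial-level dataset
#'
#' Simulates `n_agents` participants running a full experimental design:
#' within-subject designs present all three environments in blocks
#' (order shuffled per agent), between-subject designs assign one
#' environment per agent round-robin over `environments`. Each block runs
#' 8 repetitions of every capacity in the design, in shuffled order, with
#' alternative qualities redrawn from the environment prior on every trial.
#'
#' @param design A design name (`"W10"`, `"B10"`, `"W32"`, `"B32"`) or
#'   [bd_design()].
#' @param n_agents Number of simulated participants.
#' @param agent An [agent_spec()] used for every participant.
#' @param environments Environment labels cycled over agents in
#'   between-subject designs (default poor/neutral/rich).
#' @param seed Optional seed; the same seed reproduces the dataset exactly.
#' @return List with `trials` (tidy tibble, one row per trial, allocation /
#'   outcomes / truth_p as list-columns) and `truth` (per-agent generating
#'   parameters including the fraction of clamped M draws).
#' @examples
#' sim <- generate_dataset("B10", n_agents = 3, agent = agent_spec(), seed = 1)
#' nrow(sim$trials) # 3 agents x 72 trials
#' @export
generate_dataset <- function(design, n_agents, agent = agent_spec(),
                             environments = c("poor", "neutral", "rich"),
                             seed = NULL) {
  if (is.character(design)) design <- bd_design(design)
  stopifnot(inherits(design, "bd_design"), inherits(agent, "bd_agent"))
  if (!is.null(seed)) withr::local_seed(seed)
  within <- length(design$env_schedule) > 1L
  all_trials <- vector("list", n_agents)
  n_clamped <- integer(n_agents)
  n_draws <- integer(n_agents)
  for (ag in seq_len(n_agents)) {
    pid <- sprintf("agent%03d", ag)
    envs <- if (within) {
      sample(design$env_schedule)
    } else {
      environments[(ag - 1L) %% length(environments) + 1L]
    }
    rows <- list()
    for (blk in seq_along(envs)) {
      env <- bd_environment(envs[blk])
      chance <- 100 * prior_mean(env)
      caps <- sample(rep(design$capacity_set, design$reps_per_capacity))
      prev_chosen <- NULL
      prev_high <- FALSE
      for (tr in seq_along(caps)) {
        capacity <- caps[tr]
        truth_p <- draw_supplier_qualities(env, design$n_suppliers)
        dm <- draw_m(agent, capacity, design$n_suppliers)
        n_draws[ag] <- n_draws[ag] + 1L
        n_clamped[ag] <- n_clamped[ag] + dm$clamped
        force_in <- NULL
        if (!is.null(prev_chosen) && prev_high && agent$resample_bias > 0 &&
          stats::runif(1L) < agent$resample_bias) {
          force_in <- prev_chosen
        }
        alloc <- allocate_samples(dm$m, capacity, design$n_suppliers,
          split_rule = agent$split_rule,
          sequence_rule = agent$sequence_rule,
          env = env, force_include = force_in
        )
        outcomes <- stats::rbinom(capacity, 1L, truth_p[alloc])
        chosen <- .agent_choice(agent, alloc, outcomes, env)
        reward <- stats::rbinom(1L, 100L, truth_p[chosen])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant_id = pid, design = design$name,
          environment = env$label, block = blk, trial = tr,
          capacity = as.integer(capacity),
          allocation = list(as.integer(alloc)),
          outcomes = list(as.integer(outcomes)),
          chosen_supplier = as.integer(chosen),
          reward = as.integer(reward),
          truth_p = list(truth_p)
        )
        prev_chosen <- chosen
        prev_high <- reward > chance
      }
    }
    all_trials[[ag]] <- dplyr::bind_rows(rows)
  }
  trials <- dplyr::bind_rows(all_trials)
  truth <- tibble::tibble(
    participant_id = sprintf("agent%03d", seq_len(n_agents)),
    w = agent$w,
    noise_kind = agent$noise$kind,
    p = if (agent$noise$kind == "binomial") agent$noise$p else NA_real_,
    a = if (agent$noise$kind == "gaussian") agent$noise$a else NA_real_,
    b = if (agent$noise$kind == "gaussian") agent$noise$b else NA_real_,
    split_rule = agent$split_rule, sequence_rule = agent$sequence_rule,
    choice_rule = agent$choice_rule, lapse = agent$lapse,
    resample_bias = agent$resample_bias,
    frac_clamped = n_clamped / pmax(n_draws, 1L)
  )
  list(trials = trials, truth = truth)
}

#' Parameter recovery over a synthetic dataset
#'
#' Fits the free-power family to every agent to recover the exponent w (and
#' the binomial noise p), and selects the best family by cross-validated
#' log-likelihood. CVLL ties are broken toward the family with fewer free
#' parameters, then by family order.
#'
#' @param trials Trials from [generate_dataset()].
#' @param truth Matching truth table.
#' @param families Families entered in the CVLL comparison.
#' @param noise Noise model used throughout (default binomial).
#' @inheritParams compare_models
#' @return Tibble per agent: true and fitted `w` and `p`, and
#'   `selected_family`.
#' @export
parameter_recovery <- function(trials, truth,
                               families = setdiff(bd_families(), "optimal"),
                               noise = "binomial", grids = default_grids(),
                               n_folds = 4L, seed = NULL,
                               optimal_curves = NULL) {
  if (nrow(trials) == 0L) {
    return(tibble::tibble(
      participant_id = character(), w_true = numeric(), w_hat = numeric(),
      p_true = numeric(), p_hat = numeric(), selected_family = character()
    ))
  }
  cmp <- compare_models(trials,
    families = families, noise_kinds = noise, grids = grids,
    n_folds = n_folds, seed = seed, optimal_curves = optimal_curves
  )
  pick <- function(sub) {
    ok <- !is.na(sub$cvll)
    fam <- sub$family[ok]
    sc <- sub$cvll[ok]
    k <- vapply(fam, n_free_params, integer(1), noise = noise)
    top <- which(sc >= max(sc) - 1e-9)
    top <- top[order(k[top])]
    tibble::tibble(
      participant_id = sub$participant_id[1],
      selected_family = fam[top[1]],
      w_hat = sub$param[sub$family == "free_power"][1],
      p_hat = sub$p[sub$family == "free_power"][1]
    )
  }
  sel <- dplyr::bind_rows(
    lapply(split(cmp, cmp$participant_id), pick)
  )
  dplyr::left_join(
    dplyr::select(truth, "participant_id",
      w_true = "w", p_true = "p"
    ),
    sel,
    by = "participant_id"
  )
}
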