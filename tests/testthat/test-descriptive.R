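test_that("power fit recovers exponents exactly on noiseless data", {
  expect_equal(power_fit(2:10, 2:10)$exponent, 1, tolerance = 1e-12)
  caps <- c(2:10, 16, 32)
  expect_equal(power_fit(caps, caps^0.75)$exponent, 0.75, tolerance = 1e-12)
  # wide design capacity set too
  wide <- c(2, 4, 8, 16, 32)
  expect_equal(power_fit(wide, wide^0.4)$exponent, 0.4, tolerance = 1e-12)
  pf <- power_fit(caps, caps^0.6)
  expect_equal(pf$r2adj, 1, tolerance = 1e-12)
  expect_error(power_fit(2:4, c(0, 2, 3)), "m >= 1")
})

test_that("linear and piecewise fits recover noiseless generators", {
  caps <- rep(2:10, 3)
  lf <- suppressWarnings(linear_fit(caps, 2 * caps + 1))
  expect_equal(lf$a, 2, tolerance = 1e-9)
  expect_equal(lf$b, 1, tolerance = 1e-9)
  expect_error(linear_fit(c(2, 2, 3), c(1, 2, 3)), "3 distinct")

  # piecewise power law with breakpoint 6, zero noise
  caps2 <- rep(2:10, each = 4)
  m2 <- ifelse(caps2 <= 6, caps2^0.9, caps2^0.5 + 2)
  pw <- piecewise_power_fit(caps2, m2, breakpoint_grid = 3:9)
  expect_identical(pw$breakpoint, 6L)
  expect_equal(pw$a1, 0.9, tolerance = 1e-6)
  expect_equal(pw$a2, 0.5, tolerance = 1e-3)
  expect_equal(pw$b, 2, tolerance = 1e-3)
})

test_that("power-law data favour the power fit over the linear fit", {
  withr::local_seed(37)
  caps <- rep(c(2:10, 16, 32), each = 8)
  m <- pmax(1, round(caps^0.7 + stats::rnorm(length(caps), 0, 0.5)))
  expect_gte(power_fit(caps, m)$r2adj, linear_fit(caps, m)$r2adj)
})

test_that("allocation standard deviation matches worked examples", {
  expect_equal(allocation_sd(c(2, 2)), 0)
  expect_equal(allocation_sd(c(2, 1, 1)), 0.577, tolerance = 1e-3)
  expect_equal(allocation_sd(c(1, 3)), 1.41, tolerance = 1e-2)
  expect_equal(allocation_sd(5), 0) # single part: 0 by convention
})

test_that("the most even partition minimises allocation sd", {
  for (C in 4:12) {
    for (m in 2:min(C, 6)) {
      parts <- enumerate_partitions(C, m)
      parts <- parts[lengths(parts) == m]
      sds <- vapply(parts, allocation_sd, numeric(1))
      base <- C %/% m
      even <- base + (seq_len(m) <= C %% m)
      expect_equal(min(sds), allocation_sd(even), tolerance = 1e-12)
    }
  }
})

test_that("sequence classification follows the run/first-pass definitions", {
  expect_identical(classify_sequence(c(1, 1, 2, 3, 3, 4, 4)), "depth_focused")
  expect_identical(classify_sequence(c(1, 2, 3, 4, 4, 1, 3)), "breadth_focused")
  expect_identical(classify_sequence(c(1, 2, 1, 2, 3)), "mixed")
  expect_identical(classify_sequence(rep(5, 4)), "excluded") # pure depth
  expect_identical(classify_sequence(1:6), "excluded") # pure breadth
})

test_that("generated sequence rules round-trip through the classifier", {
  withr::local_seed(43)
  for (rule in c("depth_focused", "breadth_focused")) {
    for (i in 1:25) {
      C <- sample(4:10, 1)
      m <- sample(2:(C - 1), 1)
      seqn <- allocate_samples(m, C, 10,
        split_rule = "homogeneous",
        sequence_rule = rule
      )
      got <- classify_sequence(seqn)
      # a homogeneous breadth-style split with all counts 1 short of pure
      # breadth can satisfy both patterns; depth wins those ties
      expect_true(got == rule || got == "depth_focused")
      if (rule == "depth_focused") expect_identical(got, "depth_focused")
    }
  }
})

test_that("strategy fractions sum to one and respect the cell threshold", {
  agent <- agent_spec(
    w = 0.6, noise = list(kind = "binomial", p = 0.95),
    sequence_rule = "depth_focused"
  )
  sim <- generate_dataset("B10", n_agents = 4, agent = agent, seed = 47)
  fr <- strategy_fractions(sim$trials, min_trials = 10)
  expect_true(all(fr$n_trials >= 10))
  expect_equal(fr$depth_focused + fr$breadth_focused + fr$mixed,
    rep(1, nrow(fr)),
    tolerance = 1e-12
  )
  expect_true(all(fr$depth_focused == 1)) # the agent is purely depth-focused
})

test_that("deviation from optimal is zero for an optimal replayer", {
  curves <- lapply(canonical_envs, function(e) optimal_curve(e, 2:6, 10))
  curve_df <- dplyr::bind_rows(curves)
  # replay the optimal policy as trials in the poor environment
  poor <- curve_df[curve_df$environment == "poor", ]
  trials <- tibble::tibble(
    participant_id = "opt", environment = "poor",
    capacity = poor$capacity, m = poor$m_opt
  )
  dev <- deviation_from_optimal(trials, curve_df)
  expect_true(all(dev$mean_diff == 0))

  # a depth agent (m = 2) at higher capacity: M_opt - M > 0 means the
  # observed strategy is deeper than optimal
  deep <- tibble::tibble(
    participant_id = "deep", environment = "poor",
    capacity = poor$capacity, m = pmin(2L, poor$capacity)
  )
  dev2 <- deviation_from_optimal(deep, curve_df)
  expect_true(all(dev2$mean_diff[dev2$capacity >= 3] > 0))
  expect_error(
    deviation_from_optimal(
      tibble::tibble(
        participant_id = "x", environment = "poor",
        capacity = 32L, m = 2L
      ),
      curve_df
    ),
    "missing capacities"
  )
})

test_that("homogeneity and outcome comparisons use only M_opt < C trials", {
  curves <- dplyr::bind_rows(
    lapply(canonical_envs, function(e) optimal_curve(e, c(2:10, 16, 32), 32))
  )
  # an agent replaying the optimal partitions scores a zero sd difference
  rich <- curves[curves$environment == "rich", ]
  opt_trials <- tibble::tibble(
    participant_id = "opt", environment = "rich",
    capacity = rich$capacity,
    allocation = lapply(rich$partition, function(p) rep(seq_along(p), p)),
    reward = 75L
  )
  hom <- homogeneity_vs_optimal(opt_trials, curves)
  expect_equal(hom$mean_sd_diff, 0)
  # only capacities with M_opt < C qualify
  expect_identical(
    hom$n_trials,
    sum(rich$m_opt < rich$capacity)
  )

  # a homogeneous-split agent in the rich environment samples more evenly
  # than the optimal (uneven) partitions
  agent <- agent_spec(
    w = 0.5, noise = list(kind = "binomial", p = 0.95),
    split_rule = "homogeneous"
  )
  sim <- generate_dataset("B32",
    n_agents = 3, agent = agent,
    environments = "rich", seed = 53
  )
  hom2 <- homogeneity_vs_optimal(sim$trials, curves)
  expect_true(all(hom2$mean_sd_diff < 0))

  # trials at pure-breadth-optimal capacities only -> empty result + warning
  pb <- tibble::tibble(
    participant_id = "pb", environment = "poor",
    capacity = 2L, allocation = list(c(1L, 2L)), reward = 25L
  )
  expect_warning(out <- homogeneity_vs_optimal(pb, curves), "no trials")
  expect_identical(nrow(out), 0L)
})

test_that("outcome shortfall vanishes for the ideal observer and not for noise", {
  withr::local_seed(59)
  curves <- dplyr::bind_rows(
    lapply(c("poor", "rich"), function(e) optimal_curve(e, c(2:10, 16, 32), 32))
  )
  poor <- curves[curves$environment == "poor", ]
  qualifying <- poor[poor$m_opt < poor$capacity, ]

  # replay the ideal observer's partitions with normative choices: mean
  # observed reward matches the expected reward within MC error
  env <- bd_environment("poor")
  reps <- 60
  rows <- list()
  for (r in seq_len(reps)) {
    for (j in seq_len(nrow(qualifying))) {
      part <- qualifying$partition[[j]]
      alloc <- rep(seq_along(part), part)
      tr <- simulate_trial(env, qualifying$capacity[j], alloc,
        n_suppliers = 32
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = "ideal", environment = "poor",
        capacity = qualifying$capacity[j],
        allocation = list(alloc), reward = tr$reward
      )
    }
  }
  ideal <- dplyr::bind_rows(rows)
  out <- outcome_vs_optimal(ideal, curves)
  expect_lt(abs(out$mean_outcome_diff), 3.5) # ~3 s.e. of mean reward

  # a uniform-random single-sample-everywhere agent with random choice in
  # the poor environment loses reward relative to the ideal observer
  rows <- list()
  for (r in seq_len(40)) {
    for (j in seq_len(nrow(qualifying))) {
      C <- qualifying$capacity[j]
      alloc <- sample(32L, C, replace = TRUE)
      tr <- simulate_trial(env, C, alloc,
        n_suppliers = 32,
        choice_rule = function(a, o) sample(unique(a), 1L)
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = "rand", environment = "poor",
        capacity = C, allocation = list(alloc), reward = tr$reward
      )
    }
  }
  rand <- dplyr::bind_rows(rows)
  out2 <- outcome_vs_optimal(rand, curves)
  expect_lt(out2$mean_outcome_diff, 0)
})

test_that("resampling statistics detect a revisit bias and not its absence", {
  # biased agent: strongly prefers resampling the previous choice after a
  # high reward
  biased <- agent_spec(
    w = 0.6, noise = list(kind = "binomial", p = 0.9),
    resample_bias = 0.9
  )
  sim_b <- generate_dataset("B32",
    n_agents = 6, agent = biased,
    environments = "neutral", seed = 61
  )
  rs_b <- resampling_stats(sim_b$trials)
  wide_b <- tidyr::pivot_wider(rs_b[, c("participant_id", "prev_reward", "p_resample")],
    names_from = "prev_reward", values_from = "p_resample"
  )
  expect_gt(mean(wide_b$high - wide_b$low), 0)

  # history-free agent sampling among 32 alternatives: both levels similar
  flat <- agent_spec(w = 0.6, noise = list(kind = "binomial", p = 0.9))
  sim_f <- generate_dataset("B32",
    n_agents = 8, agent = flat,
    environments = "neutral", seed = 67
  )
  rs_f <- resampling_stats(sim_f$trials)
  expect_true(all(rs_f$p_resample >= 0 & rs_f$p_resample <= 1))
  expect_true(all(rs_f$frac_capacity >= 0 & rs_f$frac_capacity <= 1))
  wide_f <- tidyr::pivot_wider(rs_f[, c("participant_id", "prev_reward", "p_resample")],
    names_from = "prev_reward", values_from = "p_resample"
  )
  expect_lt(abs(mean(wide_f$high - wide_f$low)), 0.1)
})

test_that("choice agreement separates normative and proportional rules", {
  # hand-built trial where the two rules disagree (poor environment)
  tr <- tiny_trials()
  ca <- choice_agreement(tr)
  # trial 1 chose A (3/4): agrees with V_norm, disagrees with V_prop;
  # trials 2 and 3 agree with both
  expect_equal(ca$frac_norm, 1)
  expect_equal(ca$frac_prop, 2 / 3)
  expect_identical(ca$n_disagree_prop, 1L)
  expect_equal(ca$mean_extra_samples, 3) # 4 samples vs 1 on the V_prop best

  # an agent choosing by V_prop with no lapse agrees perfectly
  agent <- agent_spec(choice_rule = "v_prop", lapse = 0)
  sim <- generate_dataset("B10", n_agents = 2, agent = agent, seed = 71)
  ca2 <- choice_agreement(sim$trials)
  expect_equal(ca2$frac_prop, rep(1, 2))
})

test_that("trade-off curves respect 1 <= mean M <= C", {
  sim <- generate_dataset("W10", n_agents = 2, agent = agent_spec(), seed = 73)
  tc <- tradeoff_curve(sim$trials)
  expect_true(all(tc$mean_m >= 1))
  expect_true(all(tc$mean_m <= tc$capacity))
  expect_true(all(tc$ratio <= 1 + 1e-12))
  expect_identical(sum(tc$n_trials), nrow(sim$trials))
})
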