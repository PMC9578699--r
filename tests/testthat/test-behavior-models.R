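test_that("model families predict the documented mean M", {
  expect_equal(mean_m("free_power", 16, param = 0.5), 4)
  expect_equal(mean_m("pure_breadth", 7), 7)
  expect_equal(mean_m("depth", c(2, 10, 32)), c(2, 2, 2))
  expect_equal(mean_m("square_root", 9), 3)
  expect_equal(mean_m("linear", 10, param = 0.4), 4)
  expect_equal(mean_m("optimal", c(2, 4), m_opt = c(2, 3)), c(2, 3))
  expect_error(mean_m("optimal", 2), "m_opt")
  expect_error(mean_m("free_power", 2), "exponent")
})

test_that("gaussian log-likelihood follows the standard normal density", {
  one <- tibble::tibble(capacity = 5L, m = 5L)
  # residual 0, sigma 1 (a = 1, b = 0)
  expect_equal(
    gaussian_loglik(one, "pure_breadth", a = 1, b = 0),
    -0.5 * log(2 * pi),
    tolerance = 1e-12
  )
  # residual 1, sigma 1
  one_off <- tibble::tibble(capacity = 5L, m = 6L)
  expect_equal(
    gaussian_loglik(one_off, "pure_breadth", a = 1, b = 0),
    -0.5 * log(2 * pi) - 0.5,
    tolerance = 1e-12
  )
  # additivity over identical trials
  two <- tibble::tibble(capacity = c(5L, 5L), m = c(6L, 6L))
  expect_equal(
    gaussian_loglik(two, "pure_breadth", a = 1, b = 0),
    2 * gaussian_loglik(one_off, "pure_breadth", a = 1, b = 0),
    tolerance = 1e-12
  )
  # non-positive sigma at any capacity invalidates the parameters
  expect_identical(
    gaussian_loglik(one, "pure_breadth", a = 0.5, b = -0.2), -Inf
  )
})

test_that("binomial log-likelihood implements the impossible-event rule", {
  # p = 1 and M = M(C): the distribution is degenerate at M, LL = 0
  tr4 <- tibble::tibble(capacity = 4L, m = 4L)
  expect_equal(binomial_loglik(tr4, "pure_breadth", p = 1), 0)
  # p = 0.5, M(C) = 4 -> n = 8, P(M = 4) = choose(8,4)/2^8 = 70/256
  expect_equal(
    binomial_loglik(tr4, "pure_breadth", p = 0.5),
    log(70 / 256),
    tolerance = 1e-12
  )
  # observed M beyond n is impossible
  imp <- tibble::tibble(capacity = 9L, m = 9L)
  expect_identical(binomial_loglik(imp, "depth", p = 0.5), -Inf) # n = 4 < 9
  expect_error(binomial_loglik(tr4, "pure_breadth", p = 0), "p must lie")
})

test_that("binomial noise keeps the model mean within rounding of M(C)", {
  for (w in c(0.5, 0.75)) {
    for (p in c(0.3, 0.7, 0.9)) {
      for (C in c(2, 5, 10, 32)) {
        n <- max(1, round(C^w / p))
        expect_lte(abs(n * p - C^w), p / 2 + p) # rounding plus n >= 1 clamp
      }
    }
  }
})

test_that("AIC counts free parameters per family and noise model", {
  expect_equal(aic(-100, 1), 202)
  expect_equal(aic(-50, 2) - aic(-50, 1), 2)
  expect_identical(n_free_params("free_power", "binomial"), 2L)
  expect_identical(n_free_params("depth", "gaussian"), 2L)
  expect_identical(n_free_params("linear", "gaussian"), 3L)
  expect_identical(n_free_params("optimal", "binomial"), 1L)
})

test_that("grid fit recovers generating parameters and honours degenerate grids", {
  sim <- generate_dataset("W10",
    n_agents = 1,
    agent = agent_spec(w = 0.7, noise = list(kind = "binomial", p = 0.9)),
    seed = 41
  )
  fit <- grid_fit(sim$trials, "free_power", "binomial")
  expect_lte(abs(fit$param - 0.7), 0.05) # within one grid step
  expect_lte(abs(fit$noise_params[["p"]] - 0.9), 0.05)

  # noiseless pure breadth attains the maximum (LL = 0 at p = 1)
  nb <- tibble::tibble(capacity = rep(2:10, 4), m = rep(2:10, 4))
  fits <- lapply(
    setdiff(bd_families(), "optimal"),
    function(f) grid_fit(nb, f, "binomial")
  )
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  expect_equal(max(lls), 0)
  expect_identical(
    fits[[which.max(lls)]]$family, "pure_breadth"
  )

  # a single-point grid returns that point
  g1 <- default_grids()
  g1$w <- 0.75
  g1$p <- 0.9
  one <- grid_fit(sim$trials, "free_power", "binomial", grids = g1)
  expect_equal(one$param, 0.75)
  expect_equal(one$noise_params[["p"]], 0.9)

  # a grid under which every observation is impossible fails loudly
  g0 <- default_grids()
  g0$w <- 0.1
  g0$p <- 1
  expect_error(
    grid_fit(sim$trials, "free_power", "binomial", grids = g0),
    "-Inf likelihood"
  )
})

test_that("cross-validation partitions trials and is deterministic when noiseless", {
  nb <- tibble::tibble(
    participant_id = "p",
    capacity = rep(2:9, 4), m = rep(2:9, 4)
  )
  cv1 <- cross_validate(nb, "pure_breadth", "binomial", seed = 5)
  cv2 <- cross_validate(nb, "pure_breadth", "binomial", seed = 99)
  # deterministic data: every fold fits p = 1 and scores the test set at 0
  expect_equal(cv1$cvll, 0)
  expect_equal(cv1$cvll, cv2$cvll)
  expect_identical(cv1$n_excluded_folds, 0L)

  # folds are a partition stratified by capacity
  expect_identical(sort(unique(cv1$fold)), 1:4)
  expect_identical(length(cv1$fold), nrow(nb))
  for (cap in unique(nb$capacity)) {
    expect_identical(as.vector(table(cv1$fold[nb$capacity == cap])), rep(1L, 4))
  }
})

test_that("likelihoods are invariant to trial order", {
  sim <- generate_dataset("B10",
    n_agents = 1, agent = agent_spec(), seed = 17
  )
  tr <- sim$trials
  perm <- withr::with_seed(1, sample(nrow(tr)))
  expect_equal(
    binomial_loglik(tr, "free_power", p = 0.9, param = 0.75),
    binomial_loglik(tr[perm, ], "free_power", p = 0.9, param = 0.75)
  )
  expect_equal(
    gaussian_loglik(tr, "square_root", a = 1, b = 0.1),
    gaussian_loglik(tr[perm, ], "square_root", a = 1, b = 0.1)
  )
})

test_that("model comparison produces a tidy table and ranks the generator first", {
  withr::local_seed(23)
  agent <- agent_spec(w = 0.6, noise = list(kind = "binomial", p = 0.85))
  sim <- generate_dataset("B10", n_agents = 3, agent = agent, seed = 31)
  cmp <- compare_models(sim$trials,
    families = setdiff(bd_families(), "optimal"),
    noise_kinds = "binomial", seed = 7
  )
  expect_identical(nrow(cmp), 3L * 5L)
  best <- dplyr::slice_max(dplyr::group_by(cmp, participant_id), cvll, n = 1)
  expect_true(all(best$family == "free_power"))

  # the optimal family needs a curve and then fits too
  curves <- lapply(canonical_envs, function(e) optimal_curve(e, 2:10, 10))
  cmp_opt <- compare_models(sim$trials,
    families = "optimal", noise_kinds = "binomial",
    optimal_curves = curves, seed = 7
  )
  expect_identical(nrow(cmp_opt), 3L)
  expect_true(all(is.finite(cmp_opt$cvll)))
})
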