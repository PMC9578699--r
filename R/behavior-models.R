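#' Behavioural model families for the number of alternatives sampled
#'
#' Six families predict the mean number of alternatives sampled M as a
#' function of capacity C: `depth` (M = 2), `pure_breadth` (M = C), `linear`
#' (M = dC, free slope d), `square_root` (M = sqrt(C)), `free_power`
#' (M = C^w, free exponent w) and `optimal` (M = the ideal observer's
#' M_opt(C), supplied per trial).
#'
#' @param family Family name.
#' @param capacity Integer capacities (vectorised).
#' @param param Free parameter value (`d` for `linear`, `w` for
#'   `free_power`); ignored otherwise.
#' @param m_opt Per-capacity optimal M, aligned with `capacity`; required for
#'   the `optimal` family.
#' @return Predicted mean M, same length as `capacity`.
#' @examples
#' mean_m("free_power", 16, param = 0.5) # 4
#' mean_m("depth", c(2, 8, 32)) # 2 2 2
#' @export
mean_m <- function(family = bd_families(), capacity, param = NULL, m_opt = NULL) {
  family <- match.arg(family)
  switch(family,
    depth = rep(2, length(capacity)),
    pure_breadth = as.numeric(capacity),
    linear = {
      if (is.null(param)) stop("`linear` needs slope `param`", call. = FALSE)
      param * capacity
    },
    square_root = sqrt(capacity),
    free_power = {
      if (is.null(param)) stop("`free_power` needs exponent `param`", call. = FALSE)
      capacity^param
    },
    optimal = {
      if (is.null(m_opt) || anyNA(m_opt)) {
        stop("`optimal` family needs per-trial `m_opt` from an optimal curve",
          call. = FALSE
        )
      }
      as.numeric(m_opt)
    }
  )
}

#' @rdname mean_m
#' @export
bd_families <- function() {
  c("depth", "pure_breadth", "linear", "square_root", "free_power", "optimal")
}

#' Default parameter grids for model fitting
#'
#' Exhaustive-search grids: exponent w and slope d from 0.05 to 1.1 in steps
#' of 0.05; binomial noise p from 0.01 to 1 in steps of 0.01; Gaussian noise
#' intercept a in \[-3, 3\] and slope b in \[-1, 1\], steps of 0.05, with
#' combinations yielding a non-positive s.d. at any observed capacity
#' rejected during fitting.
#'
#' @return Named list of numeric grids (`w`, `d`, `p`, `a`, `b`).
#' @export
default_grids <- function() {
  list(
    w = seq(0.05, 1.1, by = 0.05),
    d = seq(0.05, 1.1, by = 0.05),
    p = seq(0.01, 1, by = 0.01),
    a = seq(-3, 3, by = 0.05),
    b = seq(-1, 1, by = 0.05)
  )
}

# Aggregate trials to unique (capacity, m[, m_opt]) cells with weights; the
# likelihood of every model is a weighted sum over cells, which makes the
# exhaustive grid search cheap.
.fit_cells <- function(trials, need_opt = FALSE) {
  trials <- add_m(trials)
  cols <- c("capacity", "m", if (need_opt) "m_opt")
  if (need_opt && !"m_opt" %in% names(trials)) {
    stop("`optimal` family needs an `m_opt` column (join an optimal curve first)",
      call. = FALSE
    )
  }
  agg <- dplyr::count(trials, dplyr::across(dplyr::all_of(cols)), name = "wgt")
  agg
}

#' Derive the number of alternatives sampled per trial
#'
#' Adds an `m` column (number of distinct alternatives in the allocation) to
#' a trial table if absent.
#'
#' @param trials Trial tibble with an `allocation` list-column or `m` column.
#' @return The tibble with an integer `m` column.
#' @export
add_m <- function(trials) {
  if (!"m" %in% names(trials)) {
    if (!"allocation" %in% names(trials)) {
      stop("trials need an `m` or `allocation` column", call. = FALSE)
    }
    trials$m <- vapply(trials$allocation, allocation_m, integer(1))
  }
  trials
}

#' Gaussian-noise log-likelihood of observed M
#'
#' The observed M is modelled as the family mean plus Gaussian noise whose
#' standard deviation grows linearly with capacity,
#' \eqn{\sigma_j = a + b C_j}; each trial contributes the standard normal
#' log-density \eqn{-\frac{1}{2}\log 2\pi - \log\sigma_j -
#' (M_j - M(C_j) - \mu)^2 / (2\sigma_j^2)}. Parameters giving
#' \eqn{\sigma_j \le 0} for any trial yield `-Inf`.
#'
#' @param trials Trial tibble (columns `capacity` and `m`, or an
#'   `allocation` list-column; plus `m_opt` for the `optimal` family).
#' @param family Model family, see [bd_families()].
#' @param a,b Noise intercept and slope.
#' @param param Family free parameter (slope d or exponent w).
#' @param mu Mean offset, default 0.
#' @return Total log-likelihood (scalar; `-Inf` if any sigma is invalid).
#' @export
gaussian_loglik <- function(trials, family, a, b, param = NULL, mu = 0) {
  cells <- .fit_cells(trials, need_opt = identical(family, "optimal"))
  sig <- a + b * cells$capacity
  if (any(sig <= 0)) {
    return(-Inf)
  }
  mm <- mean_m(family, cells$capacity, param = param, m_opt = cells$m_opt)
  sum(cells$wgt * stats::dnorm(cells$m, mean = mm + mu, sd = sig, log = TRUE))
}

#' Binomial-noise log-likelihood of observed M
#'
#' The observed M is modelled as Binomial(\eqn{n_j}, p) with
#' \eqn{n_j = \mathrm{round}((M(C_j) + \mu) / p)} (clamped to at least 1), so
#' its expectation matches the family mean up to rounding. A trial with
#' \eqn{M_j > n_j} is an impossible event and contributes `-Inf`.
#'
#' @inheritParams gaussian_loglik
#' @param p Binomial success probability, 0 < p <= 1.
#' @return Total log-likelihood (scalar, possibly `-Inf`).
#' @examples
#' tr <- tibble::tibble(capacity = 8L, m = 4L)
#' binomial_loglik(tr, "free_power", p = 0.5, param = 2 / 3)
#' @export
binomial_loglik <- function(trials, family, p, param = NULL, mu = 0) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]", call. = FALSE)
  cells <- .fit_cells(trials, need_opt = identical(family, "optimal"))
  mm <- mean_m(family, cells$capacity, param = param, m_opt = cells$m_opt)
  n_j <- pmax(1L, as.integer(round((mm + mu) / p)))
  if (any(cells$m > n_j)) {
    return(-Inf)
  }
  sum(cells$wgt * stats::dbinom(cells$m, n_j, p, log = TRUE))
}

.family_param_grid <- function(family, grids) {
  switch(family,
    linear = grids$d,
    free_power = grids$w,
    NA_real_ # fixed-shape families: a single placeholder "parameter"
  )
}

#' Number of free parameters of a family + noise combination
#'
#' Family parameters (1 for `linear` and `free_power`, 0 otherwise) plus
#' noise parameters (2 for Gaussian: a, b; 1 for binomial: p).
#'
#' @param family Model family.
#' @param noise `"binomial"` or `"gaussian"`.
#' @return Integer count.
#' @export
n_free_params <- function(family, noise = c("binomial", "gaussian")) {
  noise <- match.arg(noise)
  (family %in% c("linear", "free_power")) + if (noise == "gaussian") 2L else 1L
}

#' Akaike information criterion
#'
#' @param loglik Total log-likelihood.
#' @param k Number of free parameters.
#' @return AIC = 2k - 2 loglik.
#' @export
aic <- function(loglik, k) {
  2 * k - 2 * loglik
}

#' Exhaustive grid fit of one model family
#'
#' Maximises the chosen noise likelihood over the Cartesian product of the
#' family's parameter grid and the noise parameter grid(s). Ties are broken
#' toward the smallest parameter vector in lexicographic order (family
#' parameter first, then noise parameters).
#'
#' @inheritParams gaussian_loglik
#' @param noise `"binomial"` or `"gaussian"`.
#' @param grids Parameter grids, see [default_grids()].
#' @param mu Mean offset, default 0.
#' @return A list with `family`, `noise`, `param` (NA for fixed-shape
#'   families), `noise_params` (named), `loglik`, `n_trials` and `aic`.
#' @examples
#' tr <- tibble::tibble(capacity = rep(2:10, 4), m = rep(2:10, 4))
#' grid_fit(tr, "pure_breadth", "binomial")$loglik # 0 at p = 1
#' @export
grid_fit <- function(trials, family = bd_families(),
                     noise = c("binomial", "gaussian"),
                     grids = default_grids(), mu = 0) {
  family <- match.arg(family)
  noise <- match.arg(noise)
  cells <- .fit_cells(trials, need_opt = identical(family, "optimal"))
  if (nrow(cells) == 0L) stop("no trials to fit", call. = FALSE)
  fam_grid <- .family_param_grid(family, grids)
  n_trials <- sum(cells$wgt)

  best <- list(loglik = -Inf, param = NA_real_, noise_params = NULL)
  for (fp in fam_grid) {
    mm <- mean_m(family, cells$capacity,
      param = if (!is.na(fp)) fp else NULL, m_opt = cells$m_opt
    )
    if (noise == "binomial") {
      for (p in grids$p) {
        n_j <- pmax(1L, as.integer(round((mm + mu) / p)))
        if (any(cells$m > n_j)) next
        ll <- sum(cells$wgt * stats::dbinom(cells$m, n_j, p, log = TRUE))
        if (ll > best$loglik) {
          best <- list(loglik = ll, param = fp, noise_params = c(p = p))
        }
      }
    } else {
      # all (a, b) with sigma > 0 at every observed capacity, evaluated as
      # one matrix of per-cell log-densities
      ab <- expand.grid(b = grids$b, a = grids$a)[, c("a", "b")]
      ab <- ab[order(ab$a, ab$b), ]
      sig <- outer(cells$capacity, ab$b) + rep(ab$a, each = nrow(cells))
      ok <- colSums(sig <= 0) == 0L
      if (!any(ok)) next
      resid <- cells$m - mm - mu
      ll_mat <- -0.5 * log(2 * pi) - log(sig[, ok, drop = FALSE]) -
        resid^2 / (2 * sig[, ok, drop = FALSE]^2)
      ll <- colSums(cells$wgt * ll_mat)
      j <- which.max(ll) # first max = smallest (a, b) under the ordering
      if (ll[j] > best$loglik) {
        idx <- which(ok)[j]
        best <- list(
          loglik = ll[j], param = fp,
          noise_params = c(a = ab$a[idx], b = ab$b[idx])
        )
      }
    }
  }
  if (!is.finite(best$loglik)) {
    stop("grid fit failed: all parameter combinations have -Inf likelihood",
      call. = FALSE
    )
  }
  list(
    family = family, noise = noise, param = best$param,
    noise_params = best$noise_params, loglik = best$loglik,
    n_trials = n_trials,
    aic = aic(best$loglik, n_free_params(family, noise))
  )
}

#' Fourfold cross-validated log-likelihood of one model family
#'
#' Trials are split into `n_folds` non-overlapping test sets, stratified by
#' capacity so every fold sees every capacity. For each fold the model is
#' grid-fitted on the remaining trials and scored on the held-out set; the
#' CVLL is the mean test log-likelihood over folds with a finite score.
#' Folds where a held-out trial is impossible under the fitted binomial
#' noise (M > n) are recorded in `n_excluded_folds` and dropped from the
#' average; it is an error for every fold to be invalid.
#'
#' @inheritParams grid_fit
#' @param n_folds Number of folds (default 4).
#' @param seed Optional seed for the fold assignment (applied locally).
#' @return A list with `family`, `noise`, `cvll`, `fold_loglik` (per-fold
#'   test log-likelihoods), `fold` (the per-trial fold assignment),
#'   `n_excluded_folds`, plus the full-data `fit` (a [grid_fit()] result)
#'   and its `aic`.
#' @export
cross_validate <- function(trials, family = bd_families(),
                           noise = c("binomial", "gaussian"),
                           grids = default_grids(), n_folds = 4L,
                           seed = NULL, mu = 0) {
  family <- match.arg(family)
  noise <- match.arg(noise)
  trials <- add_m(trials)
  if (nrow(trials) < n_folds) stop("need at least `n_folds` trials", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  fold <- integer(nrow(trials))
  for (cap in unique(trials$capacity)) {
    idx <- which(trials$capacity == cap)
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% n_folds + 1L
  }
  fold_ll <- vapply(seq_len(n_folds), function(f) {
    fit <- grid_fit(trials[fold != f, , drop = FALSE], family, noise,
      grids = grids, mu = mu
    )
    test <- trials[fold == f, , drop = FALSE]
    if (noise == "binomial") {
      binomial_loglik(test, family,
        p = fit$noise_params[["p"]],
        param = if (!is.na(fit$param)) fit$param else NULL, mu = mu
      )
    } else {
      gaussian_loglik(test, family,
        a = fit$noise_params[["a"]], b = fit$noise_params[["b"]],
        param = if (!is.na(fit$param)) fit$param else NULL, mu = mu
      )
    }
  }, numeric(1))
  valid <- is.finite(fold_ll)
  if (!any(valid)) {
    stop("cross-validation failed: every fold has -Inf test likelihood",
      call. = FALSE
    )
  }
  full_fit <- grid_fit(trials, family, noise, grids = grids, mu = mu)
  list(
    family = family, noise = noise,
    cvll = mean(fold_ll[valid]),
    fold_loglik = fold_ll,
    fold = fold,
    n_excluded_folds = sum(!valid),
    fit = full_fit,
    aic = full_fit$aic
  )
}

#' Compare all model families on a multi-participant dataset
#'
#' Runs [cross_validate()] (and the full-data AIC) for every combination of
#' model family and noise kind, separately per participant (and per
#' environment when `by_environment = TRUE`, as in within-subject designs).
#' The `optimal` family requires `optimal_curves` so each trial can be
#' assigned its ideal-observer M_opt.
#'
#' @param trials Trial tibble with `participant_id`, `environment`,
#'   `capacity` and `allocation` (or `m`) columns.
#' @param families Families to include (default all six).
#' @param noise_kinds Noise models to include.
#' @param optimal_curves A single [optimal_curve()] tibble, or a named list
#'   of them keyed by environment label; required when `"optimal"` is among
#'   `families`.
#' @param by_environment Fit each participant-environment block separately.
#' @inheritParams cross_validate
#' @return A tidy tibble, one row per participant (x environment) x family x
#'   noise, with columns `cvll`, `n_excluded_folds`, `loglik`, `aic`,
#'   `param` and noise parameters. Participants whose fit fails are flagged
#'   with `NA` scores and a warning.
#' @export
compare_models <- function(trials, families = bd_families(),
                           noise_kinds = c("binomial", "gaussian"),
                           grids = default_grids(), n_folds = 4L,
                           seed = NULL, optimal_curves = NULL,
                           by_environment = FALSE, mu = 0) {
  trials <- add_m(trials)
  if ("optimal" %in% families) {
    trials <- join_optimal_m(trials, optimal_curves)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  group_cols <- c("participant_id", if (by_environment) "environment")
  groups <- dplyr::distinct(trials, dplyr::across(dplyr::all_of(group_cols)))
  combos <- tidyr::expand_grid(groups, family = families, noise = noise_kinds)
  rows <- purrr::pmap(combos, function(...) {
    row <- list(...)
    sub <- trials
    for (gc in group_cols) sub <- sub[sub[[gc]] == row[[gc]], , drop = FALSE]
    res <- tryCatch(
      cross_validate(sub, row$family, row$noise, grids = grids,
        n_folds = n_folds, mu = mu
      ),
      error = function(e) {
        warning("fit failed for participant ", row$participant_id, " (",
          row$family, ", ", row$noise, "): ", conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(res)) {
      return(tibble::tibble(
        cvll = NA_real_, n_excluded_folds = NA_integer_,
        loglik = NA_real_, aic = NA_real_, param = NA_real_,
        p = NA_real_, a = NA_real_, b = NA_real_
      ))
    }
    np <- res$fit$noise_params
    tibble::tibble(
      cvll = res$cvll, n_excluded_folds = res$n_excluded_folds,
      loglik = res$fit$loglik, aic = res$aic, param = res$fit$param,
      p = if ("p" %in% names(np)) np[["p"]] else NA_real_,
      a = if ("a" %in% names(np)) np[["a"]] else NA_real_,
      b = if ("b" %in% names(np)) np[["b"]] else NA_real_
    )
  })
  dplyr::bind_cols(combos, dplyr::bind_rows(rows))
}

#' Attach the ideal observer's M_opt to each trial
#'
#' @param trials Trial tibble with `environment` and `capacity` columns.
#' @param optimal_curves An [optimal_curve()] tibble or named list of them
#'   keyed by environment label.
#' @return `trials` with an `m_opt` column.
#' @export
join_optimal_m <- function(trials, optimal_curves) {
  if (is.null(optimal_curves)) {
    stop("`optimal_curves` is required for the optimal family", call. = FALSE)
  }
  if (is.data.frame(optimal_curves)) {
    curve <- optimal_curves
  } else {
    curve <- dplyr::bind_rows(optimal_curves)
  }
  lookup <- dplyr::select(curve, "environment", "capacity", "m_opt")
  out <- dplyr::left_join(
    dplyr::select(trials, -dplyr::any_of("m_opt")), lookup,
    by = c("environment", "capacity")
  )
  if (anyNA(out$m_opt)) {
    missing <- unique(out$capacity[is.na(out$m_opt)])
    stop("optimal curve is missing capacities: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out
}
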