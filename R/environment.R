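#' Task environments: Beta priors over alternative quality
#'
#' An environment defines the Beta(\eqn{\alpha}, \eqn{\beta}) prior from which
#' the success probability of every alternative is drawn independently on each
#' trial. Three canonical environments are used throughout: `poor`
#' (\eqn{\alpha = 1/3, \beta = 1}, prior mean 0.25), `neutral`
#' (\eqn{\alpha = 3, \beta = 3}, prior mean 0.50) and `rich`
#' (\eqn{\alpha = 1, \beta = 1/3}, prior mean 0.75).
#'
#' @param env A canonical label (`"poor"`, `"neutral"`, `"rich"`), an existing
#'   `bd_environment`, or `NULL` when `alpha`/`beta` are given directly.
#' @param alpha,beta Positive Beta shape parameters for a custom environment.
#' @param label Optional label for a custom environment.
#'
#' @return An object of class `bd_environment`: a list with fields `label`,
#'   `alpha` and `beta`.
#' @examples
#' bd_environment("poor")
#' bd_environment(alpha = 2, beta = 5)
#' @export
bd_environment <- function(env = NULL, alpha = NULL, beta = NULL, label = "custom") {
  if (inherits(env, "bd_environment")) {
    return(env)
  }
  if (is.character(env) && length(env) == 1L) {
    shapes <- switch(env,
      poor    = c(1 / 3, 1),
      neutral = c(3, 3),
      rich    = c(1, 1 / 3),
      NULL
    )
    if (is.null(shapes)) {
      stop("unknown environment label: '", env, "'", call. = FALSE)
    }
    alpha <- shapes[1]
    beta <- shapes[2]
    label <- env
  }
  if (is.null(alpha) || is.null(beta)) {
    stop("either a canonical label or both `alpha` and `beta` must be given",
      call. = FALSE
    )
  }
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0 ||
    !is.finite(alpha) || !is.finite(beta)) {
    stop("invalid environment: Beta shapes must be positive and finite",
      call. = FALSE
    )
  }
  structure(
    list(label = label, alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "bd_environment"
  )
}

#' @export
print.bd_environment <- function(x, ...) {
  cat(sprintf(
    "<bd_environment '%s'>  Beta(alpha = %.4g, beta = %.4g), prior mean %.3f\n",
    x$label, x$alpha, x$beta, prior_mean(x)
  ))
  invisible(x)
}

#' Prior mean of an environment
#'
#' The marginal probability that any single sample is good,
#' \eqn{\alpha / (\alpha + \beta)}.
#'
#' @param env An environment (label or `bd_environment`).
#' @return A probability in (0, 1).
#' @examples
#' prior_mean("poor") # 0.25
#' @export
prior_mean <- function(env) {
  env <- bd_environment(env)
  env$alpha / (env$alpha + env$beta)
}

#' Experimental design specifications
#'
#' The four canonical designs cross a capacity range (narrow, 2--10, with 10
#' alternatives; or wide, \{2, 4, 8, 16, 32\}, with 32 alternatives) with a
#' within-subject (three environment blocks) or between-subject (one
#' environment) schedule. Every design runs 8 repetitions of each capacity in
#' each environment block, so the per-participant trial counts are
#' W10 = 216, B10 = 72, W32 = 120 and B32 = 40.
#'
#' @param name One of `"W10"`, `"B10"`, `"W32"`, `"B32"`, or `"custom"`.
#' @param capacity_set Integer capacities (custom designs only).
#' @param n_suppliers Number of available alternatives (custom only).
#' @param reps_per_capacity Repetitions of each capacity per environment block.
#' @param env_schedule Environment labels, one per block: length 3 for
#'   within-subject designs, length 1 for between-subject designs.
#'
#' @return A `bd_design` list with fields `name`, `capacity_set`,
#'   `n_suppliers`, `reps_per_capacity`, `env_schedule` and `n_trials`.
#' @examples
#' bd_design("W10")$n_trials # 216
#' @export
bd_design <- function(name = c("W10", "B10", "W32", "B32", "custom"),
                      capacity_set = NULL, n_suppliers = NULL,
                      reps_per_capacity = 8L, env_schedule = NULL) {
  name <- match.arg(name)
  narrow <- 2:10
  wide <- c(2L, 4L, 8L, 16L, 32L)
  within <- c("poor", "neutral", "rich")
  if (name != "custom") {
    capacity_set <- if (name %in% c("W10", "B10")) narrow else wide
    n_suppliers <- if (name %in% c("W10", "B10")) 10L else 32L
    env_schedule <- if (startsWith(name, "W")) within else env_schedule %||% "neutral"
    reps_per_capacity <- 8L
  }
  if (is.null(capacity_set) || is.null(n_suppliers) || is.null(env_schedule)) {
    stop("custom designs need `capacity_set`, `n_suppliers` and `env_schedule`",
      call. = FALSE
    )
  }
  capacity_set <- sort(as.integer(capacity_set))
  if (any(capacity_set < 2L)) stop("capacities must be >= 2", call. = FALSE)
  if (max(capacity_set) > n_suppliers) {
    stop("max(capacity_set) must not exceed n_suppliers", call. = FALSE)
  }
  structure(
    list(
      name = name,
      capacity_set = capacity_set,
      n_suppliers = as.integer(n_suppliers),
      reps_per_capacity = as.integer(reps_per_capacity),
      env_schedule = env_schedule,
      n_trials = length(capacity_set) * reps_per_capacity * length(env_schedule)
    ),
    class = "bd_design"
  )
}

#' @export
print.bd_design <- function(x, ...) {
  cat(sprintf(
    "<bd_design '%s'>  capacities {%s}, %d suppliers, %d reps x %d env block(s) = %d trials\n",
    x$name, paste(x$capacity_set, collapse = ","), x$n_suppliers,
    x$reps_per_capacity, length(x$env_schedule), x$n_trials
  ))
  invisible(x)
}
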