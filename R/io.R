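#' Read and write trial tables
#'
#' The on-disk trial schema is a UTF-8 CSV with a mandatory header and one
#' row per trial: `participant_id`, `design`, `environment`, `block`,
#' `trial`, `capacity`, `allocation` (alternative indices separated by `;`
#' in allocation order, 1-based), `outcomes` (`0`/`1` separated by `;`,
#' aligned with the allocation), `chosen_supplier`, `reward`, and an
#' optional `truth_p` column (`;`-separated per-alternative success
#' probabilities, empty for real data). Alternative indices are 1-based
#' both on disk and in memory. Reading validates every row and reports the
#' offending row and column; writing is lossless (numeric truth values are
#' stored at full precision).
#'
#' @param path CSV file path.
#' @param trials A trial tibble as produced by [generate_dataset()].
#' @return `read_trials()`: a trial tibble with `allocation`, `outcomes`
#'   and `truth_p` list-columns; `write_trials()`: `path`, invisibly.
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      design = readr::col_character(),
      environment = readr::col_character(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      capacity = readr::col_integer(),
      allocation = readr::col_character(),
      outcomes = readr::col_character(),
      chosen_supplier = readr::col_integer(),
      reward = readr::col_integer(),
      truth_p = readr::col_character()
    ),
    progress = FALSE
  )
  split_int <- function(x) as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
  split_num <- function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(NULL)
    }
    as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  raw$allocation <- lapply(raw$allocation, split_int)
  raw$outcomes <- lapply(raw$outcomes, split_int)
  raw$truth_p <- if ("truth_p" %in% names(raw)) {
    lapply(raw$truth_p, split_num)
  } else {
    rep(list(NULL), nrow(raw))
  }
  for (i in seq_len(nrow(raw))) {
    alloc <- raw$allocation[[i]]
    outc <- raw$outcomes[[i]]
    if (anyNA(alloc) || length(alloc) != raw$capacity[i]) {
      stop("row ", i, ", column 'allocation': expected ", raw$capacity[i],
        " valid indices",
        call. = FALSE
      )
    }
    if (anyNA(outc) || length(outc) != raw$capacity[i] ||
      any(!outc %in% c(0L, 1L))) {
      stop("row ", i, ", column 'outcomes': expected ", raw$capacity[i],
        " 0/1 values",
        call. = FALSE
      )
    }
    if (!(raw$chosen_supplier[i] %in% alloc)) {
      stop("row ", i, ", column 'chosen_supplier': alternative ",
        raw$chosen_supplier[i], " was not sampled",
        call. = FALSE
      )
    }
    if (is.na(raw$reward[i]) || raw$reward[i] < 0L || raw$reward[i] > 100L) {
      stop("row ", i, ", column 'reward': must lie in [0, 100]", call. = FALSE)
    }
  }
  raw
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  flat <- trials
  flat$allocation <- vapply(
    trials$allocation, paste, character(1), collapse = ";"
  )
  flat$outcomes <- vapply(
    trials$outcomes, paste, character(1), collapse = ";"
  )
  flat$truth_p <- if ("truth_p" %in% names(trials)) {
    vapply(trials$truth_p, function(p) {
      if (is.null(p)) "" else paste(sprintf("%.17g", p), collapse = ";")
    }, character(1))
  } else {
    ""
  }
  flat <- flat[, c(
    "participant_id", "design", "environment", "block", "trial", "capacity",
    "allocation", "outcomes", "chosen_supplier", "reward", "truth_p"
  )]
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read and write optimal-policy tables
#'
#' A policy CSV has one row per capacity: `environment`, `capacity`,
#' `m_opt`, `partition` (`;`-separated parts), `expected_value`,
#' `expected_reward`.
#'
#' @param curve An [optimal_curve()] tibble.
#' @param path CSV file path.
#' @return `read_policy()`: the curve tibble with a `partition`
#'   list-column; `write_policy()`: `path`, invisibly.
#' @export
write_policy <- function(curve, path) {
  flat <- curve
  flat$partition <- vapply(curve$partition, paste, character(1), collapse = ";")
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      environment = readr::col_character(),
      capacity = readr::col_integer(),
      m_opt = readr::col_integer(),
      partition = readr::col_character(),
      expected_value = readr::col_double(),
      expected_reward = readr::col_double()
    ),
    progress = FALSE
  )
  raw$partition <- lapply(
    raw$partition,
    function(x) as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
  )
  raw
}
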