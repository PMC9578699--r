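# Small deterministic fixtures shared across test files.

canonical_envs <- c("poor", "neutral", "rich")

# A tiny trial table built by hand: 3 trials for one participant in the
# poor environment (used for I/O and choice-rule checks).
tiny_trials <- function() {
  tibble::tibble(
    participant_id = "p1",
    design = "custom",
    environment = "poor",
    block = 1L,
    trial = 1:3,
    capacity = c(5L, 4L, 2L),
    allocation = list(
      c(1L, 1L, 1L, 1L, 2L), # A: 4 samples, B: 1
      c(3L, 3L, 4L, 4L),
      c(5L, 6L)
    ),
    outcomes = list(
      c(1L, 1L, 1L, 0L, 1L), # A: 3/4, B: 1/1
      c(1L, 0L, 0L, 0L),
      c(0L, 0L)
    ),
    chosen_supplier = c(1L, 3L, 5L),
    reward = c(62L, 30L, 10L),
    truth_p = list(NULL, NULL, NULL)
  )
}

# Noise-free trial table following M = C^w exactly (rounded), several
# repetitions per capacity.
power_law_trials <- function(w, capacities = 2:10, reps = 4) {
  caps <- rep(capacities, each = reps)
  tibble::tibble(capacity = as.integer(caps), m = round(caps^w))
}
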