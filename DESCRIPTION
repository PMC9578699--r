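Package: breadthdepth
Title: Breadth-Depth Trade-Offs in Many-Alternative Sampling Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a decision maker with a finite sampling
    budget (capacity) splits it across many alternatives before a single
    final choice: a generative model of the sampling task with Beta-distributed
    alternative qualities and binomial sampling outcomes, an exact ideal
    observer that finds the reward-maximising integer partition of the budget
    via Beta-Binomial posterior expected-maximum computations, grid-based
    fitting and fourfold cross-validated comparison of behavioural models of
    the number of alternatives sampled, descriptive analyses of allocation
    strategies (power-law trade-off fits, allocation homogeneity, sequence
    classification, sequential effects, choice-rule agreement), and a
    synthetic-agent generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
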