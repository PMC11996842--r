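Package: qcogsim
Title: Quantum-Cognition Decision Models with Observer Perturbation and
    Non-Hermitian Collapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quantum-probability models of decision fallacies
    (the Linda conjunction fallacy, sure-thing-principle violation in the
    prisoner's dilemma) together with an observer layer: a multiplicative
    conscious-influence factor, first-order time-dependent perturbation
    theory for observer-system coupling, a non-Hermitian collapse engine
    with targeted decay operators, contextual (QBist) probability updates
    through Kraus instruments and CPTP channels, and closed-form
    observer-thermodynamics calculators (Landauer bound, one-question
    energy, Bekenstein-Hawking entropy, fitness-beats-truth probability).
    Results are tidy tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
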