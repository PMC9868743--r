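Package: culturesim
Title: Multi-Agent Active Inference Simulations of Communication and
    Cumulative Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded, configurable simulator of dyadic communication and
    population-level opinion dynamics under deep active inference. Agents hold
    binary-idea beliefs as categorical distributions, exchange noisy belief
    expressions and affective cues, select interlocutors by minimizing expected
    free energy (confirmation-biased pragmatic value against novelty-seeking
    epistemic value), and slowly learn valence likelihoods and action habits
    via Dirichlet concentration counts. Reproduces the emergence of
    generalized synchrony between interlocutors as a function of likelihood
    precision, and population segregation and majority inversion under varying
    confirmation-bias composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
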