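Package: techadopt
Title: Agent-Based Modelling of Technology Adoption with Co-Evolving
    Attitudes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the diffusion of a technological innovation through a
    heterogeneous population in which adoption decisions, personal attitudes
    and technology-specific skills co-evolve. Agents choose between an old
    and a new technology by noisy myopic best response to a utility that
    combines expected material pay-offs (with foresight about future
    benefits) and normative forces: cognitive dissonance, conformity with
    peers' actions and attitudes, and conformity with an external authority.
    Skills follow a learning-by-doing / knowledge-depreciation recursion,
    and attitudes follow a linear social-influence update. The package
    provides closed-form equilibrium results for the symmetric error-free
    case (extinction attitude, an instability condition, the coexistence
    band and its adopter/non-adopter attitudes), a replicate and
    parameter-sweep harness for policy interventions (training, subsidies,
    peer-visibility, opinion-exchange and authority-effort factors), early
    adopter profiling, and nested model variants with fixed or absent
    attitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
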