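Package: polarmove
Title: Movement Analysis of Satellite-Tagged Polar Bears from Fur- and
    Ear-Mounted Telemetry Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing irregular Argos and GPS satellite telemetry
    from fur- and ear-mounted tags on polar bears during the Hudson Bay
    ice-free season. Implements the full analysis chain: post-capture
    truncation, McConnell root-mean-square speed filtering, terrestrial/foray
    selection, gap-based track segmentation, continuous-time correlated
    random walk (CTCRW) regularization of fixes onto an exact 4-hour grid,
    two-state hidden Markov models of step lengths (gamma) and turn angles
    (von Mises) with temperature-dependent transition probabilities, AICc
    model selection, Viterbi decoding and behavioural time budgets, and tag
    functional-duration and Argos error-class summaries. A synthetic-study
    generator reproduces the statistical structure of such telemetry
    (duty cycles, class-structured positional error, missed fixes, tag
    detachment) so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
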