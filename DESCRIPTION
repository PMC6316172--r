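Package: abnsynth
Title: Synthesis and Interrogation of Abstract Boolean Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Abstract Boolean Networks (ABNs) of transcription-factor
    circuits from correlation-based interaction calls, encodes experimental
    observations as bounded synchronous-trajectory constraints, and uses a
    built-in CDCL satisfiability solver to synthesise the set of concrete
    Boolean models consistent with those constraints (the constrained ABN).
    The constrained model set is interrogated through hypothesis/null
    satisfiability queries to predict gene-activation timing, factor
    essentiality and reprogramming-cocktail outcomes, with asynchronous
    simulation of single models for cross-validation and a synthetic-data
    generator for end-to-end validation of the pipeline. Motivated by the
    transcription-factor network governing maintenance and induction of naive
    pluripotency in mouse embryonic stem cells.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
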