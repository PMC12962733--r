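Package: epimem
Title: Hierarchical Active Inference Simulation of Episodic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates episodic memory as inference in a two-timescale
    (deep temporal) discrete active-inference model. A synthetic agent walks a
    Y-junction task, is later questioned about it, and answers by
    reconstructing (replaying) the episode from a compressed slow-level
    representation. Provides exact per-policy forward-backward state inference
    over factored hidden states, expected-free-energy policy selection,
    descending/ascending messages linking the two levels, syntax-conditioned
    sensory attenuation, four precision lesions (failure to encode, retrieve,
    attenuate, retain) with severity dose-response, phenotype metrics
    (replay fidelity, context-recovery step, transcripts), and a declarative
    model schema for user-supplied tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
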