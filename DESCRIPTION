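Package: ssv
Title: Structural Signature Variation for Enzyme Mutation Triage
Version: 0.1.0
Authors@R:
    person("SSV", "Maintainers", email = "ssv@example.org", role = c("aut", "cre"))
Description: Computes cutoff-scanning-matrix structural signatures of protein
    pockets (cumulative heavy-atom pair counts stratified by pharmacophore
    class pairs over a distance-cutoff grid), selects the nearest template
    enzyme from a curated database by Euclidean distance, and scores point
    mutations by the change in signature distance to the template set
    (the delta-delta-SSV statistic). Includes in-silico saturation
    mutagenesis over pocket residues with a lightweight geometric mutant
    builder, a post-hoc candidate filter chain (residue conservation,
    tolerated-substitution tables, predicted stability changes), benchmark
    evaluation of sign-based classifications, deterministic synthetic
    fixtures with an independent brute-force signature oracle, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
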