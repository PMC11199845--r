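Package: wallfollowr
Title: Wall-Following (Thigmotaxis) Quantification for Fish Trajectory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies wall-following (thigmotaxis) behaviour from 2-D
    animal-tracking trajectories recorded in rectangular assay arenas.
    Implements near-wall-belt event scoring with a minimum-path gate,
    six standard-length-normalised wall-following indicators,
    stimulation-zone response metrics with approach angle and distance,
    a boundary-attracted correlated-random-walk swim simulator with
    eye-morph presets, group statistics (Kruskal-Wallis with tie
    correction, Dunnett T3 pairwise comparisons, negative-binomial
    regression with AICc full model averaging), and phylogenetic-signal
    analysis (Pagel's lambda, PGLS, clade summaries) on species-mean
    behavioural traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    optparse
Config/testthat/edition: 3
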