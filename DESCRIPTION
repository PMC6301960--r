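Package: epidermsim
Title: Agent-Based Simulation of Epidermal Homeostasis on Structured
    Basement Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-dimensional center-based (off-lattice) model of
    epidermal homeostasis. Keratinocytes generated by stem cells anchored
    on a configurable basement membrane (flat, sinusoidal, or a
    textile-like fiber grid) migrate under overdamped contact mechanics,
    differentiate positionally, flatten into corneocytes forming a
    stratum-corneum sheet, and desquamate from the free surface. Includes
    histology-like morphometry readouts (layer cell counts, section areas
    per 100 micrometres with substrate exclusion, thickness profiles,
    rendered sections) and seeded experiment drivers that compare
    substrate undulation patterns with paired-seed replicates and
    ANOVA/Tukey statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
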