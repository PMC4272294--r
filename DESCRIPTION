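Package: alleleflow
Title: Allelic Richness Retention and Recovery Under Gene Flow and Genetic Drift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a single allele in a
    newly founded population growing logistically toward carrying capacity,
    subject to Wright-Fisher binomial drift and bidirectional (Poisson or
    deterministic) migration from a large static source population. Provides
    the probability of allele presence as the statistic relevant to allelic
    richness, equilibrium detection by a no-trend rule, migration-rate
    thresholds for frequency recovery (M_Q) and for 95% presence probability
    (M_95), cut-off source frequencies (Q_c), a waiting-time approximation of
    the equilibrium mean frequency with a fitted scale parameter, and Ewens
    allele-frequency-spectrum machinery that converts cut-off frequencies
    into expected allelic-richness recovery. Includes a scenario-grid driver
    with CSV/JSON serialization and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
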