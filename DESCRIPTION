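Package: chiasma
Title: Chiasma Frequency, Crossover Interference, and Focus Colocalization Statistics for Plant Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of meiotic recombination cytology in rice
    and other plants. Scores chiasmata from metaphase I bivalent shapes (rod =
    one, ring = two), tests per-cell chiasma counts against a Poisson
    distribution, compares genotypes with pooled two-sample t tests from
    summary statistics, estimates the strength of crossover interference by
    fitting a gamma renewal model to distances between adjacent
    recombination-protein foci on the synaptonemal complex, and computes
    dual-channel focus colocalization fractions. Includes a synthetic-data
    generator that simulates class I (interference-sensitive, gamma renewal)
    and class II (interference-free, Poisson) crossover placement under
    genotype-specific pathway knockouts, so every analysis can be exercised
    and calibrated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
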