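Package: clonaldrift
Title: Neutral-Drift Inference of Airway Progenitor Dynamics from
    Mitochondrially Marked Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing clone-size data from human airway
    epithelium in which clones are marked by spontaneous mitochondrial
    (cytochrome c oxidase deficiency) mutations. Implements the neutral-drift
    model of progenitor cell fate as a critical birth-death process, its
    analytic clone-size distributions under both pulse labelling and ongoing
    clone induction, exact Gillespie simulation of clones and whole-tissue
    realizations with spatial clone merger, a synthetic patient-cohort
    generator, and the fitting chain that extracts the mean clone size N(t)
    by a cutoff-robust first-incomplete-moment fit, the progenitor
    loss/replacement rate from the age trend of N(t), and the visible
    mutation rate from clone densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
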