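Package: amykin
Title: Amyloid Aggregation Kinetics and Chaperone Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of chaperone-mediated inhibition of amyloid
    formation, built around islet amyloid polypeptide (IAPP) and the
    jellyfish-shaped co-chaperone prefoldin. Provides extraction of kinetic
    parameters (lag time, growth-phase duration, maximal/average/initial
    growth rates, plateau height, acceleration maximum) from thioflavin-T
    aggregation time courses by smoothing, symmetric-difference derivatives
    and 5%-of-maximum derivative-threshold segmentation; NMR chemical-shift-
    perturbation and paramagnetic-relaxation-enhancement interface mapping;
    1:1 fast-exchange titration fitting of dissociation constants with
    bootstrap errors and a reduced two-site exchange lineshape model for
    off-rate estimation; biolayer-interferometry steady-state Langmuir fits;
    generation of ambiguous-interaction docking restraints from the NMR maps;
    peptide-construct mass and charge accounting; and a synthetic-data module
    (nucleation-elongation moment-equation simulator with inhibitor action,
    fast-exchange titration, PRE and BLI simulators) so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
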