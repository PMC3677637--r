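Package: hogadapt
Title: Dynamic Modelling of Yeast Hyperosmotic-Stress Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated kinetic model of the budding-yeast response to
    hyperosmotic stress: osmotic volume and turgor biophysics, two-reaction
    Hog1 signalling, stress-responsive gene expression (GPD1, GPD2, STL1,
    Pfk26/27), lumped glycolysis with glycerol, trehalose, ethanol and
    acetate branches, glycerol transport through Fps1 and Stl1, and biomass
    growth with carbon bookkeeping. Ships a calibrated reference
    parameterization, strain variants for the classical HOG-pathway mutants,
    stiff ODE simulation with a salt-step event, time-dependent scaled
    response coefficients with a finite-difference oracle, decomposition of
    the net intracellular glycerol flux into Fps1-, Gpd1- and other
    contributions (ternary coordinates), doubling-time and carbon-share
    analysis, multi-strain weighted least-squares parameter estimation with
    analytic scaling factors for relative measurements, a synthetic
    time-course data generator, tidy CSV readers/writers and SBML L3V1
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    minpack.lm,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
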