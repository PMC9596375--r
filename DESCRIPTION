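Package: aptaredox
Title: Reduction-Potential Shifts of Aptamer-Bound Flavins from
    Dual-Indicator Equilibration Assays
Version: 1.0.0
Authors@R:
    person("Aptaredox", "Developers", email = "aptaredox@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring how nucleic-acid aptamers shift the
    midpoint reduction potential (Em) of bound flavin cofactors.
    Provides the closed-form Nernst and thermodynamic-cycle relations
    linking an Em shift to differential oxidized/reduced binding
    affinity, a forward simulator of the xanthine-oxidase dual-indicator
    equilibration assay (time-resolved UV-Vis spectra with a reference
    dye of known potential), the isosbestic-point/Nernst-regression
    procedure that recovers Em from such spectra, and supporting
    binding-isotherm fitters (one-site isothermal titration calorimetry,
    Hill fluorescence quench, shared-amplitude in-line probing).
    Includes a command-line interface for simulation and fitting on CSV
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
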