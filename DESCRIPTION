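Package: diatomccm
Title: CO2 Concentration and Carbon Fixation in the Diatom Plastid Middle Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cell flux model of CO2 concentration in the "middle space" of
    the four-membrane diatom plastid, the compartment acidified or alkalized
    by a light-driven proton-pumping rhodopsin on the outermost plastid
    membrane. Computes temperature- and salinity-dependent carbonic-acid
    dissociation constants and the CO2 fraction of dissolved inorganic
    carbon at a given middle-space pH, solves the steady-state balance of
    CO2 diffusion into the plastid stroma against Michaelis-Menten carbon
    fixation, and sweeps middle-space pH and the Vmax/D ratio to quantify
    the fold change of the fixation rate relative to a reference pH,
    including the analytic uptake-limited and diffusion-limited bounds.
    Results are tidy tibbles with ggplot2 plotting methods, a flat key-value
    configuration format, deterministic CSV output with provenance
    sidecars, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
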