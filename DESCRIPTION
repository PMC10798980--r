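Package: cgdmd
Title: Coarse-Grained Discrete Molecular Dynamics of Cadherin Dimer
    Disruption by Amyloid Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven discrete molecular dynamics (DMD) at one bead per
    residue for studying how amyloid monomers, oligomers and fibril seeds
    perturb the strand-swapped EC1 dimer of vascular endothelial cadherin.
    Provides a synthetic-structure generator (toy dimer with a domain-swapped
    interface and calcium-site cross-links; ligand classes differing in
    rigidity and charge), a Go-model topology builder with discretized
    step potentials, an exact event-driven engine with Anderson thermostat
    and constant-force steering, and trajectory readouts: binding-frequency
    maps, censored first dissociation times, RMSF profiles and
    residue-class interaction breakdowns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
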