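Package: fepcycle
Title: Alchemical Free Energy Cycle Analysis for Relative Binding Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing alchemical free energy perturbation (FEP)
    calculations of relative binding free energies: lambda-window scheduling
    with a dual-topology coupling schedule (split electrostatics, soft-core
    van der Waals), Zwanzig and Bennett acceptance ratio (BAR) estimators
    with autocorrelation-based subsampling and root-sum-square error
    propagation, thermodynamic-cycle ddG assembly with additive
    charge-correction bookkeeping, forward/reverse work-overlap and
    hysteresis diagnostics, flat-bottom distance restraint energetics, and
    RMSD-based reverse clustering of docked ligand poses. Includes a toy
    Metropolis Monte Carlo alchemical simulator with closed-form free energy
    oracles for validation, and readers/writers for a NAMD-style fepout text
    dialect and plain CSV energy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
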