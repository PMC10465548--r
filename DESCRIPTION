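Package: phasemap
Title: Atomistic Liquid-Liquid Phase Equilibrium by FFT-Accelerated
    Test-Particle Insertion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes liquid-liquid phase diagrams of rigid, atomistically
    detailed molecules in solution. Excess chemical potentials are obtained
    by Widom test-particle insertion into sampled dense-solution
    configurations, with the translational scan over all insertion positions
    accelerated by fast Fourier transforms. Includes a Metropolis Monte
    Carlo sampler for periodic rigid-body solutions, a tail model that
    stabilises low-temperature chemical potentials by fitting the cumulative
    distribution of insertion energies, binodal/spinodal extraction by
    equal-area construction, second virial coefficients by Mayer-function
    integration, low-energy pose clustering with per-residue energy
    decomposition, and Grantham-distance sequence analysis. PQR structures,
    aligned FASTA, and deterministic toy fixtures are supported inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
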