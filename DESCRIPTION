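Package: chromotune
Title: Colour-Tuning Analysis of Retinal Chromophores in Microbial Rhodopsins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spectral tuning of the retinal chromophore in
    microbial rhodopsins such as the sodium pump KR2. Provides mutational
    spectral-shift arithmetic and additivity analysis, conjugated-chain
    geometry metrics (bond lengths, bond-length alternation, dihedral
    distortions) from PDB coordinates, a two-state point-charge surrogate for
    vertical excitation energies with geometric/electrostatic decomposition
    and per-residue charge-off contribution analysis, sequential photocycle
    simulation with SVD denoising and global multi-exponential fitting of
    transient-absorption data, hydroxylamine-bleach difference-spectrum
    analysis and ion-transport initial-slope assays, and deterministic
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
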