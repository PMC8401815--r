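Package: passivemotion
Title: Classifying Microscopic Particles as Cell-Like or Mineral-Like from
    Passive Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating non-motile micro-organisms from mineral
    grains of comparable size using only their passive motion in a quiescent
    fluid. Lateral Brownian motion yields a per-particle hydrodynamic radius
    through the Einstein-Stokes relation, axial drift yields a density
    difference from the fluid through Stokes' law, and the ratio of the two
    timescales (a particle Strouhal number) locates each particle on a
    gravity-versus-diffusion regime map. Includes a ground-truthed Langevin
    trajectory simulator emulating digital holographic microscope recordings
    (tracks and 4D intensity volumes), projection-based detection and greedy
    nearest-neighbour linking, per-track and population estimators with
    outlier filtering, a density-gap classifier, and observation-time
    planning for arbitrary gravity and temperature environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
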