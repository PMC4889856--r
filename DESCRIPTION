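Package: trajmob
Title: Trajectory-Method Collision Cross Sections and Ion Mobilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes collision cross sections of small molecular ions by the
    classical Trajectory Method (scattering of a drift-gas probe in a
    Lennard-Jones plus ion-induced-dipole potential, with orientation,
    Maxwell-Boltzmann velocity and impact-parameter averaging) and converts
    them to ion mobilities via the Mason-Schamp equation. Includes drift-time
    conversion for drift-tube instruments, the Langevin polarization-limit
    correction from nitrogen to oxygen with Blanc's-law mixing to ambient air,
    template builders for hydronium water clusters, aromatic cations and
    n-alkane cations with an attached water, and mean-unsigned-error
    comparison against packaged reference mobility tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
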