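Package: picodft
Title: Desk-Scale Kohn-Sham DFT with QM/MM Embedding, Real-Time TDDFT and
    Free-Energy Sampling
Version: 0.1.0
Authors@R:
    person("picodft", "developers", email = "picodft@example.org",
           role = c("aut", "cre"))
Description: Gaussian-basis Kohn-Sham density functional theory for small
    molecules with electrostatic-embedding QM/MM coupling, Born-Oppenheimer
    and Langevin molecular dynamics with umbrella sampling and WHAM
    free-energy profiles, real-time TDDFT electron dynamics (Verlet and
    Magnus propagators) for UV-vis absorption spectra, and
    autocorrelation-based vibrational spectra with ensemble spectral
    averaging. One- and two-electron integrals over Cartesian Gaussians
    (s, p, d) are evaluated with Obara-Saika recursions in compiled code;
    exchange-correlation (LDA and PBE) is integrated on Becke-partitioned
    atom-centered grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
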