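Package: flockspec
Title: Relaxation Spectra, Exceptional Points and Flocking Thresholds of
    Active Brownian Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the spectral analysis of the free Fokker-Planck
    operator of noisy self-propelled (active Brownian) particles in two
    dimensions.  Builds and diagonalizes the truncated non-Hermitian
    operator in the folded angular-Fourier basis (a Mathieu-type
    eigenproblem with purely imaginary parameter), detects and tracks the
    cascade of exceptional points along the activity axis, extracts the
    low- and high-activity power-law exponents of the slowest relaxation
    mode and its Fourier projections, derives mean-field flocking
    instability thresholds for alignment interactions of polar and higher
    symmetry, and validates the spectrum against perturbation theory,
    Mathieu asymptotics, a coupled-exceptional-point toy model and seeded
    Langevin simulation of free active Brownian particles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
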