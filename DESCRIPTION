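Package: unwrapnpt
Title: Consistent Unwrapping of Constant-Pressure Simulation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for unwrapping and rewrapping particle trajectories from
    molecular dynamics simulations under periodic boundary conditions with a
    fluctuating (barostat-coupled) orthorhombic box. Implements the
    toroidal-view (TOR) and lattice-view (LAT, HLAT, Kulke-Vermaas) unwrapping
    schemes together with their mutually consistent rewrapping schemes, an
    exactly solvable Gaussian fluctuating-box model that serves as a
    validation oracle, closed-form and root-solved upper bounds on the
    trajectory-output interval that keep boundary crossings resolvable,
    mean-squared-displacement and covariance-based diffusion-coefficient
    estimators with block-wise drift diagnostics that expose lattice-view
    artifacts, pair-diffusion additivity checks, make-whole/center-of-mass
    handling for molecules, and a plain-text trajectory format with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
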