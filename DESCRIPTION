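Package: phasesync
Title: Directional Periodicity Analysis and the EC-HPC PhaseSync Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying spatially periodic neural codes along movement
    directions in a two-dimensional conceptual space. Implements a cosine-grating
    grid-cell population model, path codes formed by summing grid activity along
    straight trajectories, an orientation alignment profile with threefold
    periodicity, a goal-directed vector field, and a winner-take-all navigation
    simulation. The analysis stack covers quadrature (sine/cosine) GLMs for
    grid-orientation estimation from event-related BOLD-like signals, direction-bin
    GLMs, fold-spectrum FFT analysis with label-shuffle permutation nulls and
    max-statistic family-wise error correction, directional-domain amplitude-phase
    coupling with circular-shift surrogates, zero-phase FIR band-pass filtering,
    phase-locking measures (PLV/PLI), and circular statistics (Rayleigh test,
    pairwise phase consistency, circular-circular correlation). A synthetic-data
    module generates event designs and direction-modulated BOLD-like time series
    with known ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
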