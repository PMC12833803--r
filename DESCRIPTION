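Package: transmitr
Title: Force and Displacement Transmit Functions from Equilibrium Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies frequency-dependent signal transmission between two
    sites of a protein or any viscoelastic medium from equilibrium positional
    time series. Correlation functions estimated from uniformly sampled
    trajectories are converted to causal linear response functions via the
    fluctuation-dissipation theorem, Fourier transformed, and represented
    analytically by multi-Debye relaxation fits. Force and displacement
    transmit functions, viscoelastic moduli, and a rectification factor are
    computed from fitted response triplets; time-domain transmit kernels
    support convolution with delta, step, rectangular, or arbitrary input
    force signals. Includes shift/splay/twist deformation-mode extraction
    for two-helix coiled-coil bundles with rigid-body motion removal,
    Pearson mode-coupling statistics with block-averaged standard errors,
    and an exactly discretized overdamped Langevin (Ornstein-Uhlenbeck)
    network simulator with closed-form response and transmit oracles for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    bio3d
VignetteBuilder: knitr
Config/testthat/edition: 3
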