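Package: critcov
Title: Covariance Patterns in Spatially Organized Balanced Critical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how unstructured, short-range connectivity in
    excitatory-inhibitory networks close to the edge of linear stability gives
    rise to long-range, salt-and-pepper covariance patterns. Builds spatially
    organized E-I networks on periodic lattices with distance-dependent random
    connectivity, evaluates closed-form linear-response statistics of pairwise
    covariances (mean and variance versus distance, Pade-based effective decay
    constants, Bessel-function long-range laws), simulates linear and
    threshold-linear (ReLU) rate networks driven by white noise, implements the
    paired two-network working-point experiment that probes the sensitivity of
    covariance patterns to firing-rate changes, and provides an analysis
    pipeline for multielectrode-array spike data: waveform-based unit
    classification, spike-count covariances, distance-resolved variance with
    finite-sample bias correction, weighted exponential decay fits, and
    within- versus between-epoch comparison statistics. A synthetic
    Utah-array-style data generator with known ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
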