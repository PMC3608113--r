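Package: misovolterra
Title: MISO Volterra Modeling of Subharmonic and Ultraharmonic Microbubble Echoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear system identification of ultrasound contrast-agent
    (microbubble) echo signals with discrete Volterra series. A third-order
    single-input single-output (SISO) Volterra model can only reproduce
    spectral lines at integer multiples of the transmit frequency; this
    package implements the multiple-input single-output (MISO) extension in
    which the excitation is split into periodic, mutually orthogonal
    sub-inputs carrying a spectral component at the subharmonic frequency,
    so that sub- and ultraharmonics (f0/2, 3f0/2, 5f0/2, ...) become
    representable. Two orthogonal decompositions are provided (period-gated
    rectangular and Hilbert-quadrature), together with least-squares kernel
    identification via a rank-revealing pseudo-inverse, a shell-modified
    Rayleigh-Plesset microbubble echo simulator, and a relative mean-square
    error evaluation harness over memory, noise level and repeated noise
    realizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    generics,
    utils,
    withr
Suggests:
    tidyr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
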