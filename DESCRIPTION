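Package: mdstream
Title: Streaming Multidimensional Arrays and Real-Time Radial MRI Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streaming framework for multidimensional complex arrays:
    slicing with serial numbers and axis bitmasks, BART-compatible cfl/hdr
    file I/O, a wire protocol that connects processing stages through pipes
    and named FIFOs, and a loop driver that applies any tool slice by slice,
    optionally in parallel workers and on live streams.  On top of this sits
    a real-time radial MRI reconstruction toolkit: Ram-Lak filtering and
    adjoint NUFFT gridding, root-sum-of-squares coil combination, SVD coil
    compression with temporal alignment of the compression matrices,
    RING-style gradient-delay estimation and trajectory correction, a
    simplified real-time nonlinear inversion (RT-NLINV), temporal median and
    frame-wise non-local means filters, a radial FLASH simulator for
    turn-based and rational golden-angle trajectories, and latency
    instrumentation with steady-state extraction and cross-correlation lag
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
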