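Package: paesim
Title: Simulation and Processing for Optical-Heterodyne Photoacoustic Endoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the detection chain of a fiber-laser ultrasound sensor
    read out by optical heterodyne detection (pressure to optical-phase
    transduction with a frequency-ratio gain, dual-polarization beat carrier
    with laser noise) and the processing pipeline of an optical-resolution
    photoacoustic endoscope: I/Q phase demodulation, hydrophone-referenced
    response calibration, noise-equivalent pressure density (NEPD) and r.m.s.
    NEP, dual-wavelength hemoglobin oxygen-saturation unmixing over raster and
    rotational-pullback scan geometries, blade-edge resolution estimation, and
    vessel segmentation statistics. All inputs are generated internally from
    digital vasculature and blade-edge phantoms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    minpack.lm,
    pracma,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
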