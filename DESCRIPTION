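Package: dropwave
Title: Quantification of Chemical Oscillations and Wave Propagation in
    Droplet Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Belousov-Zhabotinsky (BZ) oscillations in
    arrays of ferroin-catalysed droplets confined in template slots. Builds
    space-time plots (kymographs) from time-lapse frame stacks by strip
    cropping, extracts per-droplet blue-channel intensity traces, performs
    low-pass filtering, running-minimum baseline correction, peak and trough
    detection with optional manual curation, per-oscillation frequency
    estimation, lifecycle segmentation into induction, initial, main, late
    and exhausted periods, and summarises the wave features (lifetime,
    median frequency, wave count, median amplitude, median area). Tracks
    travelling oxidation wavefronts across multi-droplet kymographs and
    classifies interdroplet propagation, wave origins and annihilation
    events. A synthetic droplet-array generator with machine-readable ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
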