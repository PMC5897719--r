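Package: camech
Title: Calcium-Imaging Event Detection and Membrane-Tension Analysis for
    Mechano-Sensitized Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the analysis of spontaneous calcium
    activity in cultured neuronal networks expressing mechanosensitive ion
    channels, together with the membrane-tension biophysics of pressure-clamp
    experiments. Detects somatic regions of interest from time-lapse
    fluorescence movies via standard-deviation projection and grayscale
    morphological opening, normalizes traces to dF/F0 with a diffusion-based
    baseline, de-noises them with a one-dimensional Perona-Malik filter, and
    detects calcium events with a four-condition derivative detector to yield
    rasters and mean firing rates. Also provides a Laplace-law membrane-tension
    estimator for pipette aspiration, automated activation-pressure threshold
    detection from pressure/current recordings, and the supporting statistics
    (exact/approximate Mann-Whitney test, mean +/- s.e.m. summaries, Pearson
    colocalization). A synthetic-data module generates movies, pressure ramps
    and two-channel image pairs with full ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
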