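Package: meaflow
Title: Microelectrode-Array Network Activity Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-well microelectrode-array (MEA)
    recordings of cultured neuronal networks: consensus spike detection
    combining an amplitude threshold with a stationary-wavelet Teager energy
    operator (SWTTEO) detector, logISI burst detection with a minimum-spike
    rule and a short-burst merge rule, spike time tiling coefficient (STTC)
    synchrony, correlated spectral entropy (CorSE) functional connectivity,
    and principal-component analysis of a seven-feature activity vector.
    Includes a synthetic MEA generator (spike trains and raw voltage traces)
    with phenotype presets so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
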