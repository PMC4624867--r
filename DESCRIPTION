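Package: plinet
Title: Phase Lag Index Connectivity and Weighted Graph Analysis of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes phase lag index (PLI) functional connectivity from
    multichannel resting-state EEG in six canonical frequency bands,
    summarizes connectivity into short- and long-distance region-grouped
    averages over a 10-10 montage, characterizes the PLI-weighted network
    by its weighted clustering coefficient and characteristic path length,
    and runs the corresponding group-comparison and correlation statistics.
    Includes a seeded coupled-oscillator EEG simulator with known
    ground-truth coupling for end-to-end validation, a preprocessing chain
    (re-referencing, notch, anti-aliased downsampling, zero-phase band
    filtering, segment extraction), EDF and delimited-text I/O, and a
    reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
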