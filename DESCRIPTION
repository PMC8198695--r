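Package: ocrcaller
Title: Detect Open Chromatin Regions from Plasma Cell-Free DNA Fragmentomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects open chromatin regions (OCRs) genome-wide from plasma
    cell-free DNA (cfDNA) fragment coordinates. Computes per-base window
    protection score (WPS) and sequencing-coverage tracks over 20 kb genome
    tiles, detrends and smooths the WPS waveform with a Savitzky-Golay
    filter, locates nucleosome peaks and troughs, calls candidate OCRs from
    peakless low-coverage gaps flanked by regular nucleosome arrays, and
    filters false positives with waveform-geometry and coverage-trend
    features scored by a random-forest classifier. Includes a synthetic
    cfDNA fragment simulator with planted OCR ground truth and interval
    overlap metrics for benchmarking, plus BED/bedGraph import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
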