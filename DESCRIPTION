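Package: varnuc
Title: Nucleosome Positioning and Histone-Variant Enrichment from Tiling-Array ChIP Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls well-positioned single nucleosomes from normalized
    ChIP-chip tiling signal by Savitzky-Golay smoothing, derivative
    zero-crossing detection and parabola fitting; scores each nucleosome for
    histone-variant (H3.3) enrichment against a bulk-histone control with a
    matched IgG noise score; deconvolves the score distribution with a
    two-component Gaussian mixture and applies dual posterior/noise selection
    criteria; associates selected nucleosomes with the nearest annotated
    feature and classifies promoter versus transcription-termination-site
    positions; and computes metagene profiles with percentage-scaled gene
    bodies, expression-quantile bins and expression entropy. Includes a
    synthetic-data generator that plants nucleosome footprints on a tiled
    genome so the whole pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    signal,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
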