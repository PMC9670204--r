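Package: lysoclust
Title: Quantification of Perinuclear Lysosomal Clustering, Calcium Spikes,
    and Phosphopeptide Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying oxidative-stress-induced perinuclear
    lysosomal clustering from multichannel fluorescence microscopy fields
    (lysosome-marker intensity within a circular region of interest centred
    on the microtubule-organising centre, relative to whole-cell intensity),
    for detecting calcium spikes in dual-excitation ratiometric (Fura-2)
    time series, for relative quantification of phosphopeptides from
    data-independent-acquisition peak-area tables via top-3
    unmodified-peptide normalization, and for the accompanying many-to-one
    and all-pairs multiple-comparison statistics (Wilcoxon, Dunnett, Steel,
    Tukey-Kramer).  A synthetic-data module generates microscopy fields,
    ratio traces, peptide tables and grouped scalars with planted ground
    truth so that every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mvtnorm,
    multcomp
Config/testthat/edition: 3
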