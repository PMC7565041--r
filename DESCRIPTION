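Package: flimfret
Title: FLIM-FRET Quantification of Nanoscale Chromatin Compaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of time-correlated single photon
    counting (TCSPC) fluorescence lifetime imaging (FLIM) data for
    FRET-based readouts of nanoscale chromatin compaction, as used in
    two-fluorophore histone (GFP-H2B / mCherry-H2B) assays in the
    C. elegans germline. Provides a synthetic TCSPC scene generator with
    known per-pixel FRET ground truth, Poisson maximum-likelihood mono-
    and bi-exponential decay fitting with spatial binning and optional
    Gaussian instrument response, per-pixel FRET-efficiency maps
    (E = 1 - tauDA/tauD) against a mono-exponential donor-only
    reference, FRET-population classification (sub-low, low,
    intermediate, high) per nucleus ROI, and the group-comparison
    statistics used for genotype contrasts (unpaired t tests,
    Bonferroni, Kruskal-Wallis gated Wilcoxon, chi-square with
    Benjamini-Hochberg FDR, and qPCR relative quantification with two
    reference genes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
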