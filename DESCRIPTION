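Package: thymoflow
Title: Flow-Cytometry Identification and Quantitation of Human Thymic Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and quantifying human thymic stromal cell
    populations from multi-parameter flow cytometry. Implements a hierarchical
    gating scheme for thymic epithelial cells (cTEC/mTEC, via podoplanin, EpCAM,
    CD49f and CD200) and accessory populations (fibroblasts, vascular and
    lymphatic endothelium, dendritic cells, macrophages, thymocyte subsets),
    surface-marker screen analytics based on MFI-ratio ranking, cohort-level
    quantitation with group comparisons and correlations, qPCR relative
    quantification (2^-ddCt), and a population-exclusive transcript filter for
    FPKM expression matrices. A synthetic-data module generates cytometry
    samples, screening plates, expression matrices and donor cohorts with known
    ground truth so that every analysis stage can be validated end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
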