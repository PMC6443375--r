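Package: cytoBridge
Title: Cross-Platform Import, Export and Interchange of Gated Cytometry Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An interchange engine for gated flow and mass cytometry
    analyses. Reads raw FCS 3.0/3.1 files together with gated analyses
    (gates, gating hierarchy, display transformations, spillover
    compensation) stored in Gating-ML 2.0, FlowJo-dialect (.wsp) or
    Cytobank-dialect workspaces (including ACS containers), reproduces
    per-event population membership in R, supports modification of the
    hierarchy including attachment of high-dimensional clustering
    results, and exports back to any supported dialect. Includes a
    synthetic-data module generating FCS/workspace fixture pairs with
    ground-truth event labels from Gaussian mixtures under a known
    spillover matrix, and a command-line interface for conversion,
    population statistics and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, xml2, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
biocViews: FlowCytometry, DataImport, Preprocessing
RoxygenNote: 7.3.3
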