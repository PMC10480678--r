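Package: PEThabitus
Title: Simulation-Based Optimisation of PET Activity Administration for
    Patient Habitus
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation framework for studying how the injected
    activity of [68Ga]Ga-DOTA-TOC interacts with patient body habitus in PET
    imaging. Builds voxel code-image phantom cohorts with liver tumours,
    paints SUV-based activity distributions, simulates Poisson-noise PET
    acquisition with 511 keV attenuation, reconstructs with ordered-subsets
    expectation maximisation, and measures NEMA-style liver SNR and
    tumour-to-liver CNR. Normalised SNR is fitted with a body-size power law
    to derive an activity-administration protocol that yields a constant
    liver SNR irrespective of habitus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PEThabitus-package.R'
    'RcppExports.R'
    'activityModel.R'
    'bodyMetrics.R'
    'io.R'
    'iqMetrics.R'
    'methods.R'
    'nema.R'
    'petSim.R'
    'phantomBuilder.R'
    'pipeline.R'
    'protocolEngine.R'
    'reconstruct.R'
    'structureTable.R'
    'tumourModel.R'
    'utils.R'
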