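Package: icetrack
Title: Iterative Confidence Enhancement of Tractography on Synthetic Fiber Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Probabilistic FACT-style streamline tractography with Probabilistic
    Index of Connectivity (PICo) connection-confidence maps, and the ICE-T
    iterative seed-region-growing framework that removes the path-length
    dependency (PLD) confound from white-matter tract segmentation. Includes
    synthetic fiber-orientation phantoms (straight, crossing and branching
    bundles with ground-truth masks and centerlines) so that every stage of the
    pipeline can be exercised and validated without real diffusion MRI data,
    along with along-tract profile analysis, linear path-length compensation,
    parameter-sweep experiments, and NIfTI/TCK input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'pico.R'
    'analysis.R'
    'phantom.R'
    'tracking.R'
    'icet.R'
    'config.R'
    'icetrack-package.R'
    'io-tracks.R'
    'io-volumes.R'
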