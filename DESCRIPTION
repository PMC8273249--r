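Package: spfdeeg
Title: EEG Source Localization with a Finite-Difference Volume Conductor and Matching Pursuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based scalar-potential finite-difference (SPFD) forward
    modeling of EEG with successive over-relaxation and geometric multigrid
    solvers, reciprocity-based lead-field matrix construction, and greedy
    matching-pursuit source localization. Includes synthetic layered-sphere
    head phantoms (segmented, homogeneous, CSF-insert, and smoothed
    "segmentation-free" conductivity variants), international 10-20 / 10-10
    electrode montage placement, and a Monte-Carlo evaluation harness for
    localization error under additive Gaussian noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
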