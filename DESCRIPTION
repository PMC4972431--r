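Package: surfseed
Title: Surface-Based fMRI-Seeded Diffusion Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds grey-matter/white-matter interface meshes from tissue
    segmentations, fits block-design task-fMRI general linear models
    directly on the cortical mesh with framewise-displacement motion
    censoring and Laplace-Beltrami surface smoothing, seeds streamline
    tractography from significant activation patches under anatomical
    mesh constraints, classifies streamlines into corticomotor and
    thalamocortical tracts with a two-stage weighted k-means, and derives
    tract-level diffusion statistics (dispersion, FA/MD asymmetry
    indices) for correlation with clinical scores. Includes synthetic
    phantom generators for every input so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, RNifti, jsonlite, igraph, xml2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
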