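Package: fsubr
Title: Functional Sub-Bundle Extraction from Diffusion MRI Tractograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the functional sub-bundle (FSuB) of a white-matter
    tractogram: the streamlines whose endpoints connect to one or two
    functionally defined cortical regions at the gray-matter-white-matter
    interface (GMWMI). Provides readers and writers for TCK and TRK
    tractograms, FreeSurfer binary surfaces and .label files, and NIfTI
    volumes; computes a probabilistic GMWMI from a five-tissue-type
    segmentation; projects surface ROIs into the interface along vertex
    normals; matches streamline endpoints to target voxels by radial,
    forward, or exact-endpoint search; and summarises results as
    bundle-level connectivity profiles. A deterministic slab phantom
    generator supplies synthetic meshes, segmentations, statistical maps
    and tractograms with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
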