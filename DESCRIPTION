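Package: qatrack
Title: Quantitative-Anisotropy-Aided Deterministic Fiber Tracking for
    Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstruction and deterministic tractography for diffusion
    MRI. Implements generalized q-sampling reconstruction of per-voxel spin
    distribution functions, per-orientation quantitative anisotropy (QA),
    diffusion tensor / fractional anisotropy and q-ball / generalized
    fractional anisotropy maps, and a generalized streamline tracker that
    filters fiber orientations by QA or by voxel-level indices (FA, GFA,
    anatomy) with trilinear or nearest-neighbour interpolation and a
    weight-based termination criterion. Includes multi-compartment DWI
    phantom simulators (crossing bundles in free water, multi-strand
    spindle) with Rician noise, threshold calibration against a reference
    mask, region-wise index statistics, bootstrap confidence intervals for
    false-track proportions, and readers/writers for NIfTI, FSL
    bval/bvec, TRK and TCK formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
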