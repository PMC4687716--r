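Package: hydikit
Title: Multi-Shell Hybrid Diffusion MRI Reconstruction and Shell-Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hybrid diffusion imaging (HYDI) acquisitions that sample
    several concentric q-space shells. Simulates multi-shell diffusion-weighted
    phantoms with two-compartment decay and Rician noise, reads and writes
    NIfTI-1 volumes with FSL-style bvals/bvecs gradient tables, constructs
    cumulative shell subsets, fits diffusion tensors by weighted least squares,
    reconstructs orientation distribution functions by analytic q-ball imaging
    with Laplace-Beltrami regularized spherical harmonics, computes FA, MD, RD,
    AX, GFA and normalized quantitative anisotropy maps, measures angular
    deviation between shell schemes, runs deterministic streamline tractography
    with anisotropy stopping criteria, and provides voxel-wise shell-trend
    regression with Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, RNifti, pracma, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
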