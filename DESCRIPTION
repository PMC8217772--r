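Package: petquant
Title: Semi-Automated Atlas-Based Quantification of Small-Animal Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A semi-automated pipeline for preclinical dynamic PET brain
    studies in rodents. Dynamic PET volumes are preprocessed (peripheral
    slice exclusion, speckle removal, frame summation, within-group
    intensity normalisation), the brain volume of interest is segmented by
    rotational contour matching against a resized MRI atlas (with distinct
    procedures for metabolic and target-selective radiotracers), a PET
    template is built from the control group by deformable registration and
    co-registered to the MRI atlas space in two affine steps, atlas labels
    are transferred to the PET grid with per-voxel fractional membership,
    and tracer uptake is quantified per atlas sub-region with three
    semi-quantitative parameters (normalized activity, standardized uptake
    value, uptake ratio) followed by automated nonparametric or parametric
    group statistics with normality diagnostics and plot output. A digital
    phantom generator provides synthetic MRI/atlas/PET cohorts with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
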