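Package: amypvc
Title: Partial-Volume Correction and Early-Signal Detection for Amyloid PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxel-based partial-volume correction (two-compartment
    Meltzer-type and three-compartment Mueller-Gartner-type) for amyloid
    PET, six-variant SUVR quantification against whole-cerebellum and
    white-matter reference regions, linear-spline and dependent-correlation
    association analyses of SUVR with CSF Abeta42, and a ranked
    sliding-window voxel-wise procedure locating the highest CSF Abeta42
    level at which regional tracer elevations first reach significance.
    Includes a digital brain phantom simulator that generates cohorts of
    PSF-blurred, noisy PET volumes with a latent amyloid burden coupled to
    CSF Abeta42, so every analysis is testable end to end without access
    to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    igraph,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
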