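Package: vtamap
Title: Sweet-Spot Mapping of Deep Brain Stimulation Volumes of Tissue
    Activated
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based lesion-symptom mapping (VLSM) of deep brain
    stimulation outcomes. Estimates binary volumes of tissue activated
    (VTAs) from stimulation current with a point-source electric-field
    model, runs voxel-wise stimulated-versus-non-stimulated tests with
    covariates and a minimum-group-size rule, corrects clusters for
    family-wise error by permutation of the outcome vector, and applies a
    distance-based single-subject prediction rule to new patients.
    Includes a synthetic-cohort generator with planted voxel-cluster
    effects so the whole pipeline can be exercised and validated without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
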