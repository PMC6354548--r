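Package: BrainVolReport
Title: Automated Radiologic Sentences from Regional Brain Volumetry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts per-structure brain MRI volume tables into human-readable
    radiologic sentences about atrophy and ventricular enlargement. Base
    segmentation volumes are aggregated through an ontology of anatomic
    superstructures (gyri to lobes to hemispheres), normalized to total brain
    volume, and scored against an age-linear normative model fitted on a
    control cohort; thresholded z-scores drive a rule-based clinical knowledge
    filter that triggers direct, relational (hemispheric/prominent) and
    combination (lobe-specific) sentences through a template dictionary.
    Includes an evaluation module (contingency tables, agreement metrics,
    Cohen's kappa, three-rater majority voting, and a decision-tree
    discrepancy categorizer) and a synthetic-cohort simulator with injectable
    atrophy patterns for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
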