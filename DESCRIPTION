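Package: dbsorient
Title: Orientation of Directional Deep-Brain-Stimulation Leads from
    Postoperative CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated detection of the rotational (yaw) orientation of
    a directional deep-brain-stimulation lead from a postoperative CT volume.
    Given a CT scan in NIfTI format and two points on the lead trajectory, the
    pipeline refines the trajectory from the metal hyperdensity, auto-selects
    the artifact slices, estimates the two inverse candidate orientations from
    the 180-degree-periodic streak artifact of the stereotactic marker via
    circular-harmonic phase analysis, and resolves the remaining ambiguity
    with four independent methods (center-of-mass shift, sagittal
    center-of-mass, asymmetric marker sampling, and dark-star streak
    similarity). A synthetic CT phantom generator with known ground-truth
    orientation makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse
Config/testthat/edition: 3
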