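Package: pmctviz
Title: Automated Gas, Bone and Foreign-Body Overview Images from Postmortem CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates color-coded 2D overview images from postmortem computed
    tomography (PMCT) volumes of the thorax and abdomen. Air outside the body
    (including the hollow, air-filled interior of the scanner table) is removed
    by seeded region growing from the volume corners and from automatically
    detected table seeds. Maximum-intensity, selective minimum-intensity and
    average orthographic projections are then computed for anterior-posterior
    and lateral views and composited into a single RGB image per view: windowed
    gray levels give anatomical context, radiopaque material (metal implants,
    projectiles) is painted red and intracorporeal gas blue. Includes a
    parametric synthetic CT phantom generator with ground-truth masks, readers
    for NIfTI volumes and single-frame CT DICOM series, PNG export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
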