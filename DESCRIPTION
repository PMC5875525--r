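Package: acrqa
Title: Automated Image-Quality Assurance for the ACR CT Accreditation
    Phantom on CT and CBCT Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated routine image-quality assurance for fan-beam CT
    simulators and linac-mounted cone-beam CT (CBCT) systems using the ACR
    CT accreditation phantom (model 464). Reads axial DICOM series, locates
    the phantom and its alignment/distance ball bearings, and computes the
    full QA measurement panel: Hounsfield-unit accuracy for the five density
    plugs, contrast-to-noise ratio and noise for the polyethylene and
    acrylic plugs, image uniformity, in-plane distance accuracy, slice
    thickness from the wire ramps, low-contrast rod visibility, and
    high-contrast bar-pattern resolution. A statistical-process-control
    layer maintains per-machine baselines, derives quantitative tolerance
    bands as twice the maximum observed standard deviation, evaluates
    sessions against them, and produces longitudinal trend reports. A
    synthetic phantom renderer with controllable noise, resolution,
    cupping/crescent artifacts and session-to-session drift emulates scanner
    data so the whole pipeline is testable without a scanner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
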