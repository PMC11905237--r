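Package: seccheck
Title: Secondary Dose and Monitor-Unit Verification for a 1.5 T MR-Linac
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Independent secondary dose and monitor-unit (MU) verification
    engine and commissioning toolkit for a 1.5 T MR-linear accelerator
    (Elekta Unity class, 7 MV FFF). Houses a beam model (calibration,
    percent depth-dose and output-factor tables, MLC transmission and
    dosimetric leaf gap, gantry-angle cryostat correction, magnetic-field
    aware profile model), a TG-71-style point-dose factorization with a
    finite-size pencil-beam aperture integrator, plan-level MU and point-dose
    tolerance checking with automatic point-of-interest selection, 1-D and
    2-D global gamma analysis, and the commissioning procedures used to
    build the model (DLG optimization, MLC transmission derivation,
    cryostat normalization, PDD comparison). Reads a JSON/CSV beam-model
    dialect, a JSON plan dialect, and a DICOM-RT-Plan subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
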