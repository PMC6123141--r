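Package: rtdvh
Title: Radiotherapy DVH Database and Plan Analytics from DICOM-RT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Imports non-image DICOM radiotherapy filesets (RT Plan, RT
    Structure Set, RT Dose), computes cumulative dose-volume histograms by
    rasterizing planar contours onto the dose grid, derives geometric metrics
    (PTV union, PTV overlap volume, ROI-to-PTV surface distances) and
    radiobiological metrics (gEUD, TCP, NTCP), and persists everything in a
    five-table relational schema keyed by medical record number and study
    instance UID. A query and statistics layer provides DVH endpoint tables,
    interquartile DVH bands, time-series with moving averages, two-group
    tests, correlation matrices and linear regressions. Synthetic DICOM-RT
    phantom generators with analytic ground truth make the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    DBI,
    RSQLite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
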