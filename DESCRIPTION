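Package: tagmapr
Title: Declarative TagMap-Driven Export of Radiotherapy Archives to DICOM-RT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Translates proprietary-style tomotherapy patient archives into
    linked, standards-compliant DICOM-RT objects using human-readable XML
    data maps ("TagMaps").  Each TagMap pairs the DICOM tags of one object
    type with literal values or queries (XPath over archive XML, or a SQL
    subset over relational fixtures); the engine builds a query-bearing
    DICOM skeleton and evaluates it in document order against a pluggable
    backend.  Includes the numeric transformations the export requires:
    16-bit dose-grid quantization with a DoseGridScaling factor,
    multileaf-collimator plan-sinogram decoding across two storage
    generations, couch-insertion image padding, and timestamp-fallback
    relinking of image-guidance positional corrections.  Ships a synthetic
    archive generator (the "tomo-lite" dialect) with ground-truth manifests
    so the whole pipeline is testable without any clinical data, plus a
    batch export front-end with QA accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
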