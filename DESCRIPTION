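Package: imgstudy
Title: DICOM Metadata to FHIR ImagingStudy Pipeline with Quality Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit that turns directories of DICOM Part-10
    objects into pseudonymized HL7 FHIR R4 "ImagingStudy" transaction bundles
    and profiles the completeness of the imaging metadata they carry. It
    parses DICOM headers without decoding pixel data, groups instances into
    the study/series hierarchy, maps Body Part Examined and Laterality values
    to SNOMED CT concepts, hashes instance-hierarchy UIDs into a derived UID
    namespace, replaces patient identifiers and accession numbers through a
    persisted pseudonym map, orchestrates sequential study processing against
    a transfer manifest with completeness verification, and computes a
    metadata-quality report (modality, body-region and laterality completion
    rates, and the laterality distribution over paired body regions). A
    deterministic synthetic-corpus generator emulating a multi-department
    radiology workload is included for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
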