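Package: toxiquant
Title: Targeted LC-MS/MS Quantification, Validation and Elimination
    Kinetics for Anticoagulant Rodenticides
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for a six-compound anticoagulant
    rodenticide panel (coumatetralyl, bromadiolone, difenacoum,
    flocoumafen, brodifacoum, difethialone) measured by multiple
    reaction monitoring LC-MS/MS in blood and faeces. Implements
    weighted second-order calibration with back-calculation, limit of
    quantification and ion-ratio quality control, the bioanalytical
    validation battery (within-/between-day precision, bias, and the
    Matuszewski post-extraction spike design for matrix effect and
    extraction recovery), multi-aliquot faecal aggregation, and
    censoring-aware multiphasic elimination half-life estimation from
    serial samples. A seeded synthetic-data generator stands in for the
    instrument and the animal, producing calibration series, quality
    control replicates, matrix-experiment sets, and biphasic
    concentration-time profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
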