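Package: dieltime
Title: Molecular Timetable Analysis of Diel Transcriptome Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects periodically expressed genes in diel (day/night)
    expression time courses by fitting a bank of phase-shifted 24-h cosine
    templates, selects high-amplitude time-indicating genes, and estimates
    a sample's internal circadian time from a single snapshot of normalized
    expression (the molecular timetable method). Includes RPKM
    normalization, low-expression filtering, day-to-day stability
    diagnostics, a ground-truth synthetic time-course generator, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
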