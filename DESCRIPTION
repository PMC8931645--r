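Package: vpsmetrics
Title: Learning Analytics for Virtual-Patient Simulation Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores student action logs from virtual-patient clinical
    simulations against an author-defined case answer key. Computes
    per-section sensitivity, precision and F1 for the seven phases of a
    simulated encounter (input scenario, anamnesis, physical examination,
    medical tests, hypothesis generation, binary analysis, final
    diagnosis), combines them into overall, collection and analytical
    composite scores, and derives a methodological score from the
    student's section execution string via normalized Levenshtein
    similarity to reference workflow patterns. Includes critical
    diagnostic act path analysis against a desired execution path,
    cohort-level reporting (score distributions, radar data, ranks, path
    frequency tables), Spearman rank validation against external exam
    scores, and a parameterized synthetic-cohort generator so the whole
    pipeline is testable without real student data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
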