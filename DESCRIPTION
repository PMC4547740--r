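Package: adrcorpus
Title: Ground-Truth Corpora of Temporal Correlations Between Drug
    Administrations and Laboratory Value Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating ground-truth corpora of
    temporal correlations between drug administration episodes and
    laboratory value changes in electronic health records. Mines solitary
    drug administration episodes from day-stamped event streams, attaches
    and normalizes laboratory curves to patient-specific reference
    intervals, aggregates multi-rater nominal classifications into
    majority calls with concordance values and rule-based intricacy
    levels, and provides the evaluation statistics used to compare
    external (e.g. algorithmic) assessments against the expert ground
    truth: a difficulty-weighted Concordance Score, Krippendorff's alpha
    for nominal data, and Pearson chi-squared tests on 2x2 tables. A
    synthetic EHR generator with a simulated rater panel makes the whole
    pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
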