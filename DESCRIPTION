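Package: heightage
Title: Height-Age and Proportion of Maximal Benefit for Child Growth Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-expresses child linear growth outcomes from randomized trials on
    the height-age scale. Derives group-level height-age (the age at which a
    growth standard's median stature equals the group's observed mean stature)
    from mean height, mean height-for-age z-scores, or individual-level records
    against an LMS growth reference, with confidence-interval propagation
    throughout; handles the recumbent-length/standing-height transition at two
    years of age; and scores intervention effects with the proportion of maximal
    benefit (PMB), which compares the intervention group's change in height-age
    with the biologically optimal rate of one day of height-age per day of
    chronologic age. Includes a synthetic-data generator for references, cohorts
    and two-arm trials with known ground truth, and a command-line pipeline that
    turns trial summary tables into effect tables and height-age-for-age plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
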