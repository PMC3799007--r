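Package: pstpupil
Title: Simulation and Pupillometric Analysis of Processing Speed Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing a pupillometric study of
    processing speed training on a modified useful-field-of-view (UFOV)
    paradigm. Implements the trial paradigm (timing, four task levels,
    peripheral layout, fixed test schedules), the adaptive dual-response
    training staircase with its stimulus-duration ladder, a synthetic-data
    generator producing psychometric observer responses and 1000 Hz pupil and
    gaze sample streams with load-dependent task-evoked dilation, a pupil
    measurement pipeline (dispersion-based fixation detection, a fixed
    pre-probe window of interest, percent change from the Task 2 reference),
    and the matching statistics: within-subject (Cousineau-Morey) standard
    errors, balanced split-plot repeated-measures ANOVA, and paired and
    two-sample t tests. A workflow layer runs the full synthetic study
    end to end and renders summary, ANOVA, and training-trend tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
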