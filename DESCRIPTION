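Package: manopull
Title: Pull-Through Anorectal Manometry: Simulation, Sphincter Metrics and
    Diagnostic Cut-Off Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel pull-through anorectal
    manometry in infants with a suspected anterior anus. Locates the
    high-pressure zone of the anal sphincter complex in eight-channel
    radial pressure recordings, computes mean circumferential and mean
    anterior pressures and their ratio, aggregates maneuvers per patient,
    and evaluates a combined cut-off rule for an anus outside the
    sphincter complex with exact Clopper-Pearson confidence intervals.
    Group comparisons use a tie-corrected Mann-Whitney U test and the
    Pearson chi-square test for 2x2 tables, both implemented from first
    principles. A synthetic-cohort generator produces pull-through
    recordings with the axial-by-angular pressure structure the analysis
    assumes, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
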