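Package: qsardb
Title: Create, Store, Validate and Analyse QSAR Model Archives
Version: 0.1.0
Authors@R:
    person("QsarDB", "Maintainers", email = "maintainers@qsardb.example.org",
           role = c("aut", "cre"))
Description: Tools for the QsarDB (QDB) archive format, a container/cargo
    data model for quantitative structure-activity relationship (QSAR)
    data sets and models. Provides the typed container hierarchy
    (compounds, properties, descriptors, models, predictions), directory
    and ZIP storage backends following the QDB path conventions, codecs
    for the system cargo formats (tab-separated parameter tables, UCUM
    unit strings, BibTeX references, BODO descriptor-ontology records,
    chemical structure attachments), a linear-regression PMML subset with
    a prediction evaluator, archive-wide integrity validation including
    CAS registry number checksums, conversion of tabular raw data into
    archives, on-demand goodness-of-fit statistics, label queries, a
    synthetic-archive generator and a command-line toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    xml2,
    yaml,
    zip
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
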