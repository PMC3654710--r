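Package: roadmapr
Title: Temporal RDF Road Maps of HTTP File Repositories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Crawls hierarchical data repositories exposed as HTTP
    directory listings (or local trees and recursive index files),
    represents every file and folder as RDF with deterministic UUID
    identifiers and temporal provenance (first-seen, last-seen,
    last-modified), keeps the graph current through incremental
    re-scrapes, and answers reproducibility queries (file sets as of a
    date, removed files) and dashboard statistics (growth and doubling
    time, platform-by-disease incidence).  Ships a deterministic
    synthetic repository generator and server, modelled on the
    seven-level disease-study / center-type / center-domain / platform /
    data-type / archive / file layout used by large cancer genomics
    repositories, for testing crawlers end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    curl,
    uuid,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    httpuv,
    callr,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
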