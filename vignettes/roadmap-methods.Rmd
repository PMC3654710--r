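---
title: "Temporal RDF road maps of file repositories: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal RDF road maps of file repositories: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadmapr)
```

## The problem

Large genomics consortia publish their files through plain HTTP
directory trees whose *layout is itself metadata*: in the cancer-atlas
convention a file's path encodes, level by level, the disease study
(`gbm`, `ov`, `kich`, `ucec`, ...), the center type (`cgcc`, `gsc`,
`bcr`), the submitting center's domain, the assay platform
(`mda_rppa_core`, `genome_wide_snp_6`, ...), the data type, and the
release archive that bundles files published together.  The files
themselves are stable; their *locations and availability* are not —
archives are reorganised, bad submissions replaced, whole subtrees
retired.  An analysis that cites "the repository as of last March" is
irreproducible unless something has been watching.

`roadmapr` is that watcher.  It crawls such a tree, represents every
file and folder as RDF, and maintains three provenance dates per
resource: when the engine first saw it, when it last saw it, and the
upstream modified date the server reports.  From those three dates the
graph answers the questions reproducibility needs: *which files existed
at time t*, and *which files have since been removed*.

## The data model

Every resource becomes a subject `tcga:<uuid>` with exactly six
single-valued properties — `rdf:type`, `rdfs:label`, `tcga:url`,
`tcga:firstSeen`, `tcga:lastSeen`, `tcga:lastModified` — and, for files
only, up to six link properties (`tcga:diseaseStudy` ...
`tcga:archive`) pointing at the typed ancestors on the file's path.
The type is a pure function of depth below the root: directories at
depths 1–6 are `DiseaseStudy`, `CenterType`, `CenterDomain`,
`Platform`, `DataType`, `Archive`; deeper non-directories are `File`.
Link-property names are the class names with the first letter
lower-cased.  Directories deeper than the archive level get no typed
record but are still traversed; files beneath them link to the depth-6
archive.  This keeps the class vocabulary closed at exactly seven
kinds.

Identifiers are deliberately *semantically neutral*: a name-based
(SHA-1, RFC 4122 version 5) UUID of the normalized URL under a fixed
namespace.  Two consequences drive this choice.  First, the identifier
leaks no repository semantics, so renames and re-renderings of the
listing never invalidate statements about a resource; provenance lives
in triples, not in URI syntax.  Second, minting is deterministic and
stateless: two independent crawls of the same tree build
triple-for-triple identical graphs (up to date literals), and a known
URL is always recognised as an update rather than re-minted, without
consulting any stored state.  URL normalization — lower-cased scheme
and host, default port and trailing slash stripped, percent-encoding
canonicalised — defines the identity key; its main risk is that a
folder URL recorded without its trailing slash will not compare
byte-for-byte with sources that keep it, which we accept for the sake
of stable identity across listing dialects.

## Scrape semantics

A scrape walks the tree depth-first, parents before children, each
directory fetched exactly once (a visited-set over normalized URLs
guards against cycles).  One timestamp is fixed at crawl start and
stamped on every entry of that crawl, which makes "the latest
last-seen date" a well-defined equivalence class and makes a
same-timestamp rerun exactly idempotent.  For a known URL only
`tcga:lastSeen` and `tcga:lastModified` are rewritten; `tcga:firstSeen`
is write-once.  Resources absent from a crawl are left untouched — a
stale last-seen date *is* the removal record.

Two temporal queries follow directly:

* **removed resources**: everything whose last-seen date precedes the
  newest last-seen date in the graph;
* **as-of resolution**: in `first_seen` mode, files with
  `firstSeen <= t` and `lastSeen >= t` (presence is observable only at
  scrape granularity); in `last_modified` mode, files with
  `lastModified <= t`, which reconstructs repository states that
  predate the first scrape from upstream dates alone.

One caveat is inherent to the model rather than the implementation: a
file removed and later re-added at the same URL resumes its old record
(the UUID and first-seen date are identity), so the absence interval is
recoverable only at scrape granularity.  Likewise a modified file at an
unchanged URL is an update, not a new resource; strict
content-versioning (new URL per content change) would be an extension,
not the present behaviour.

## Storage and querying

The graph lives in an in-memory triple table with two derived indexes
(normalized URL → UUID, kind → UUIDs) that are always rederivable from
the triples; `auditGraph()` checks cardinality (exactly one of each
record property per subject), referential integrity of file links, and
index consistency.  Serialization formats are sorted N-Triples (the
sort makes output byte-reproducible, so graph equality is file
equality), Turtle, and RDF/XML; the vocabulary contains no blank nodes,
so round-trip isomorphism reduces to triple-set equality.

Queries are answered by an embedded SPARQL evaluator covering the
subset a closed seven-class vocabulary needs: `PREFIX`, `SELECT`
(`DISTINCT`, `ORDER BY`, `LIMIT`/`OFFSET`) and `ASK`, basic graph
patterns, and `FILTER` with comparison and boolean operators.
`OPTIONAL`, property paths, aggregation and federation are out of
scope.  Date literals are ISO-8601 UTC strings, which compare correctly
as plain strings — a deliberate choice that keeps filter evaluation
free of timezone arithmetic.  Correctness of the evaluator is checked
two independent ways in the test suite: against a naive backtracking
triple-scan evaluator over a hand-written query corpus, and against
Python `rdflib` parsing our own serializations.

## Dashboard statistics

`growthSeries()` counts files by the UTC calendar day of first sighting
(or of upstream modification, for pre-scrape history) and accumulates;
removals never shrink it, because it counts appearances, not presence.
`doublingTime()` fits `log2(count)` against time in days by ordinary
least squares and returns the reciprocal slope.  OLS on the log scale
is the simplest estimator consistent with exponential growth: it is
exact on noiseless exponentials (the tests check recovery of 30-, 210-
and 400-day doubling periods to machine precision) and degrades
gracefully under multiplicative noise (±5% noise over 50 points
recovers a 210-day period within 5%).  A numerically flat or negative
slope raises a no-growth error rather than returning a meaningless
period.

`platformDiseaseIncidence()` computes the bipartite disease × platform
structure — an edge wherever at least one file links both — twice: by
direct index scan and by SPARQL, with `method = "both"` asserting the
two agree.  Nodes are identified by label, as dashboards display
labels, and the kinds partition the label sets so collisions cannot
occur.

## The synthetic repository

`generateRepository()` builds a deterministic seven-level tree with
labels drawn from realistic vocabularies, so fixtures read like the
real thing.  The default conditions — 4 disease studies × 2 center
types × 2 center domains × 3 platforms × 2 data types × 2 archives × 3
files, i.e. 364 directories and 576 files — were chosen once as a
desk-scale tree that is deep enough to exercise every schema level and
broad enough to give the incidence statistics non-trivial structure,
while a full scrape stays in the seconds range.  Platform sets are
drawn per center-domain branch (the same disease reached through
different centers uses overlapping but distinct platforms), or can be
designed exactly via `platformSets` when a test needs a known incidence
matrix.

`evolveRepository()` applies add/remove/touch events under an injected
logical clock — never wall-clock — so every temporal scenario replays
deterministically.  Folder modified dates follow listing semantics: a
folder's date is the time its set of *immediate* children last changed,
so additions and removals stamp the direct parent only, and touching a
file stamps nothing but the file.  The event log replays from the
initial tree to any time point (`replayNodes()`, `trueFileSet()`),
which is what makes the repository its own oracle: engine results are
compared not with the engine but with log replay.

The fixture can be rendered as autoindex HTML (Apache `<pre>` and table
variants, nginx, bare anchors), as a recursive `ls -Rl`-style index
file, materialized to a real directory tree, or served over local HTTP
from a background process with a request counter — which makes the
crawler's efficiency contract (requests = directories + 1) directly
measurable.

What the fixture does *not* emulate: authentication and controlled
access, compressed archive bundles alongside expanded directories,
exotic listing dialects, server clock skew, and content beyond
placeholder payloads.  Passing tests therefore demonstrate the engine's
bookkeeping and temporal logic, not robustness to every autoindex
dialect in the wild; the listing parser is written to be tolerant
(fallback href-scraping) but real deployments should expect to extend
it.

## Numerical and engineering choices

* All timestamps are UTC; listing dates without timezone are assumed
  UTC.  Apache/nginx listing dates carry minute precision, index files
  full seconds; the engine treats whichever it gets as the upstream
  modified date.
* Politeness: the crawler is single-threaded with a configurable delay
  (default 0.1 s) between HTTP fetches, and an index-file crawl needs
  one request in total — both bowing to the burden repeated re-scraping
  places on public servers.
* Fetch failures are retried (`maxRetries`, default 3); a directory
  that ultimately fails becomes an error event and its subtree is
  skipped while siblings continue; only an unreachable root is fatal.
* Problem sizes in the test suite (tiny trees for unit tests, 25 random
  specs for crawl completeness, 50 random evolution scenarios of 3–6
  scrapes for the temporal properties, 500 records for the schema
  round-trip) were chosen as the smallest sizes that still exercise
  every code path several times over.

## A worked micro-example

```{r}
repo <- generateRepository(c(1, 1, 1, 1, 1, 1), filesPerArchive = 2, seed = 7)
tp <- repoTransport(repo)
src <- crawlSource("http", tp$baseURL, politenessDelay = 0,
                   transport = tp$transport)
res <- updateRoadmap(roadmapGraph(), src,
                     as.POSIXct("2012-02-01", tz = "UTC"))
res$report
countByKind(res$graph)
queryGraph(res$graph,
           "SELECT ?l WHERE { ?s rdf:type tcga:File . ?s rdfs:label ?l }")
```

## Known limitations

The store is in-memory and single-writer; persistence is by explicit
serialization, and a hosted SPARQL endpoint would be an adapter, not a
replacement, for the embedded evaluator.  The SPARQL subset is
documented above and deliberately small.  Removal detection is
scrape-granular: what happens between two scrapes is invisible.  And
the seven-kind schema is a convention of the crawled layout — trees
that do not follow it are still indexed (typed by depth), but the type
names will only be as meaningful as the layout is.
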