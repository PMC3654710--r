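# roadmapr

**A self-updating, queryable road map of an HTTP file repository, with
temporal provenance for reproducible analysis.**

Genomics consortia expose their open-access data as plain HTTP
directory trees whose layout *is* the metadata: in the cancer-atlas
convention a file's path spells out, level by level, the disease study
(`gbm`, `ov`, `kich`, `ucec`, ...), center type, center domain, assay
platform (`mda_rppa_core`, `genome_wide_snp_6`, ...), data type, and
release archive.  The tree is fluid — files are added, replaced and
retired continuously — so any analysis that wants to be reproducible
needs a record of *what was available when*.

`roadmapr` crawls such a tree (live over HTTP, from a local mirror, or
from a single `ls -Rl`-style index file), represents every file and
folder as RDF, and keeps the graph current through incremental
re-scrapes.  It is aimed at bioinformaticians and data engineers who
need programmatic, versioned discovery of repository subsets rather
than portal clicking or bulk mirroring.

## The model

Each resource is a subject `tcga:<uuid>` carrying exactly six
single-valued properties

```
rdf:type           one of tcga:{DiseaseStudy, CenterType, CenterDomain,
                               Platform, DataType, Archive, File}
                   (determined purely by depth in the tree)
rdfs:label         the resource's name (final path segment)
tcga:url           its URL
tcga:firstSeen     first scrape that included the resource
tcga:lastSeen      most recent scrape that included it
tcga:lastModified  upstream modified date from the listing
```

plus, for `tcga:File` subjects only, link triples `tcga:diseaseStudy`,
`tcga:centerType`, `tcga:centerDomain`, `tcga:platform`,
`tcga:dataType`, `tcga:archive` pointing at the typed ancestors on the
file's path.  UUIDs are name-based (SHA-1, RFC 4122 v5) over the
normalized URL: deterministic, stateless, and semantically neutral —
"cool" identifiers that never change and leak nothing.

The three dates make the graph a temporal index:

* **as-of resolution** — files available at time *t* are those with
  `firstSeen <= t <= lastSeen` (or `lastModified <= t`, to reconstruct
  states predating the first scrape);
* **removal detection** — resources whose `lastSeen` lags the newest
  `lastSeen` in the graph were dropped upstream;
* **dashboard statistics** — cumulative growth with a doubling-time
  estimate (OLS fit of log2 count against days, doubling time = 1 /
  slope), and the disease × platform bipartite incidence, computed both
  by SPARQL and by direct index scan.

Queries run on an embedded SPARQL SELECT/ASK evaluator (basic graph
patterns, FILTER, DISTINCT, ORDER BY, LIMIT); graphs serialize to
sorted (byte-reproducible) N-Triples, Turtle and RDF/XML.

## Worked example

The package ships a deterministic synthetic repository that mimics the
seven-level layout — it is both a demo target and the oracle for the
whole test suite.

```r
library(roadmapr)

repo <- generateRepository(c(2, 1, 1, 2, 1, 1), filesPerArchive = 2, seed = 1)
tp   <- repoTransport(repo)                  # in-process HTTP transport
src  <- crawlSource("http", tp$baseURL, politenessDelay = 0,
                    transport = tp$transport)
res  <- updateRoadmap(roadmapGraph(), src,
                      as.POSIXct("2012-02-01", tz = "UTC"))
res$report
#> ScrapeReport @ 2012-02-01T00:00:00Z
#>   added: 26  updated: 0  errors: 0
#>   DiseaseStudy  2
#>   CenterType    2
#>   ...
#>   File          8
```

26 resources were new (2 disease studies down to 8 files), yielding a
graph of 204 triples.  The dashboard incidence, computed by SPARQL and
index scan and cross-checked:

```r
platformDiseaseIncidence(res$graph, method = "both")$edges
#>   disease               platform
#> 1    kich       affymetrix_u133a
#> 2    kich     agilentg4502a_07_3
#> 3    kirc illuminahiseq_rnaseqv2
#> 4    kirc               mirnaseq
```

Remove a file upstream, rescrape a month later, and the temporal
queries answer both reproducibility questions:

```r
f     <- repoNodes(repo)$path[!repoNodes(repo)$isDirectory][1]
repo2 <- evolveRepository(repo, list(list(advance = 86400),
                                     list(remove = f)))
tp2   <- repoTransport(repo2)
g2 <- updateRoadmap(res$graph,
                    crawlSource("http", tp2$baseURL, politenessDelay = 0,
                                transport = tp2$transport),
                    as.POSIXct("2012-03-01", tz = "UTC"))$graph

detectRemoved(g2)[, c("kind", "label", "lastSeen")]
#>   kind                                  label   lastSeen
#> 1 File bcgsc.ca.affymetrix_u133a.data_105.txt 2012-02-01

nrow(resolveAsOf(g2, as.POSIXct("2012-02-01", tz = "UTC")))  # 8 files then
#> [1] 8
nrow(resolveAsOf(g2, as.POSIXct("2012-03-01", tz = "UTC")))  # 7 files now
#> [1] 7
```

The removed file is reported with its stale last-seen date, and the
as-of query returns the 8-file set an analysis dated 2012-02-01 would
have used.

## Command line

A thin CLI over the same functions lives at `inst/scripts/roadmap`:

```sh
roadmap scrape  --root http://host/tcga/ --store graph.ttl
roadmap removed --store graph.ttl
roadmap asof    --store graph.ttl --date 2012-02-01T00:00:00Z
roadmap query   -f graph.ttl -q query.rq
roadmap stats   growth --store graph.ttl --csv
roadmap fixture generate --out /tmp/tree --seed 7
```

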