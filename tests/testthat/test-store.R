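graph_from_records <- function(records) {
  g <- roadmapGraph()
  for (r in records) g <- upsertResource(g, r)
  g
}

test_that("upsert inserts unknown resources and updates only the seen dates", {
  rec <- resourceRecord("http://x.org/gbm", "DiseaseStudy", t0())
  g <- upsertResource(roadmapGraph(), rec)
  expect_identical(nTriples(g), 6L)
  later <- resourceRecord("http://x.org/gbm", "DiseaseStudy",
                          firstSeen = t0() + days(5),
                          lastModified = t0() + days(3))
  g2 <- upsertResource(g, later)
  expect_identical(nTriples(g2), 6L)
  rec2 <- recordsFromGraph(g2, recordUUID(rec))[[1]]
  d <- recordDates(rec2)
  expect_identical(unname(d["firstSeen"]), t0())          # write-once
  expect_identical(unname(d["lastSeen"]), t0() + days(5)) # refreshed
  expect_identical(unname(d["lastModified"]), t0() + days(3))
  expect_identical(recordUUID(rec2), recordUUID(rec))
})

test_that("re-typing a known URL is a conflict", {
  g <- upsertResource(roadmapGraph(),
                      resourceRecord("http://x.org/gbm", "DiseaseStudy", t0()))
  expect_error(
    upsertResource(g, resourceRecord("http://x.org/gbm", "Platform", t0())),
    class = "roadmapr_kind_conflict")
})

test_that("insertion order does not affect the graph", {
  set.seed(99)
  records <- lapply(1:100, random_record)
  g1 <- graph_from_records(records)
  g2 <- graph_from_records(rev(records))
  expect_identical(serializeGraph(g1, "ntriples"),
                   serializeGraph(g2, "ntriples"))
  expect_true(isomorphicGraphs(g1, g2))
})

test_that("the audit catches cardinality, referential and index drift", {
  repo <- tiny_repo()
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  expect_true(auditGraph(g))
  ## duplicate a single-valued predicate
  bad <- g
  bad@triples <- rbind(bad@triples, bad@triples[bad@triples$p == "rdfs:label", ][1, ])
  expect_error(auditGraph(bad), "cardinality")
  ## point a link at a subject of the wrong class
  bad2 <- g
  i <- which(bad2@triples$p == "tcga:platform")[1]
  wrong <- paste0("tcga:", uuidsOfKind(g, "Archive")[1])
  bad2@triples$o[i] <- wrong
  expect_error(auditGraph(bad2), "referential")
  ## index drift
  bad3 <- g
  bad3@urlIndex <- bad3@urlIndex[-1]
  expect_error(auditGraph(bad3), "index drift")
})

test_that("all three serializations round-trip isomorphically", {
  repo <- generateRepository(c(2, 1, 1, 2, 1, 1), filesPerArchive = 2,
                             seed = 21)
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  for (fmt in c("ntriples", "turtle", "rdfxml")) {
    doc <- serializeGraph(g, fmt)
    g2 <- loadGraph(doc, fmt)
    expect_true(isomorphicGraphs(g, g2), info = fmt)
    ## auto-detection finds the format
    expect_true(isomorphicGraphs(g, loadGraph(doc)), info = fmt)
  }
  ## empty graph round-trips to an empty graph
  for (fmt in c("ntriples", "turtle", "rdfxml"))
    expect_identical(nTriples(loadGraph(serializeGraph(roadmapGraph(), fmt),
                                        fmt)), 0L)
  expect_error(serializeGraph(g, "json"))
})

test_that("sorted N-Triples output is byte-stable", {
  repo <- tiny_repo()
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  expect_identical(serializeGraph(g, "ntriples"), serializeGraph(g, "ntriples"))
  ## and through a file
  f <- withr::local_tempfile(fileext = ".nt")
  serializeGraph(g, "ntriples", file = f)
  expect_identical(readChar(f, file.size(f), useBytes = TRUE),
                   serializeGraph(g, "ntriples"))
})

test_that("the evaluator agrees with a naive triple-scan on a query corpus", {
  repo <- generateRepository(c(2, 1, 1, 2, 1, 1), filesPerArchive = 2,
                             seed = 31)
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  corpus <- c(
    "SELECT ?s WHERE { ?s rdf:type tcga:Platform }",
    "SELECT ?l WHERE { ?s rdf:type tcga:DiseaseStudy . ?s rdfs:label ?l }",
    "SELECT DISTINCT ?d ?p WHERE { ?f rdf:type tcga:File . ?f tcga:diseaseStudy ?ds . ?ds rdfs:label ?d . ?f tcga:platform ?pl . ?pl rdfs:label ?p }",
    "SELECT ?f ?a WHERE { ?f tcga:archive ?a }",
    "SELECT ?s ?u WHERE { ?s tcga:url ?u . FILTER(?u != \"nothing\") }",
    "SELECT ?s WHERE { ?s tcga:firstSeen ?d . FILTER(?d >= \"2012-01-02T00:00:00Z\"^^xsd:dateTime) }",
    "SELECT ?l WHERE { ?s rdfs:label ?l . ?s rdf:type tcga:Archive . FILTER(?l != \"x\" && ?l != \"y\") }",
    "SELECT * WHERE { ?s rdf:type tcga:CenterDomain . ?s rdfs:label ?l }",
    "SELECT ?t WHERE { ?s rdf:type ?t . ?s rdfs:label \"gbm\" }",
    "SELECT ?f WHERE { ?f rdf:type tcga:File . ?f tcga:platform ?p . ?p rdfs:label \"mda_rppa_core\" }"
  )
  for (q in corpus)
    expect_identical(result_rows(queryGraph(g, q)), naive_sparql(g, q),
                     info = q)
  ## ASK agreement
  expect_identical(queryGraph(g, "ASK { ?s rdf:type tcga:File }"),
                   naive_sparql(g, "ASK { ?s rdf:type tcga:File }"))
  expect_false(queryGraph(g, "ASK { tcga:no-such-uuid rdf:type tcga:File }"))
})

test_that("SELECT modifiers order, page and deduplicate", {
  repo <- tiny_repo()
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  res <- queryGraph(g, "SELECT ?l WHERE { ?s rdfs:label ?l } ORDER BY ?l")
  expect_identical(res$l, sort(res$l))
  lim <- queryGraph(g,
    "SELECT ?l WHERE { ?s rdfs:label ?l } ORDER BY ?l LIMIT 3 OFFSET 1")
  expect_identical(lim$l, sort(res$l)[2:4])
  desc <- queryGraph(g, "SELECT ?l WHERE { ?s rdfs:label ?l } ORDER BY DESC(?l)")
  expect_identical(desc$l, rev(sort(res$l)))
})

test_that("syntax errors carry a position", {
  g <- roadmapGraph()
  err <- tryCatch(queryGraph(g, "SELECT ?x WHERE { ?x rdf:type }"),
                  error = identity)
  expect_s3_class(err, "roadmapr_sparql_error")
  expect_match(conditionMessage(err), "position [0-9]+")
  expect_error(queryGraph(g, "DESCRIBE ?x"), class = "roadmapr_sparql_error")
})

test_that("rdflib parses our serializations and agrees on query results", {
  repo <- generateRepository(c(2, 1, 1, 2, 1, 1), filesPerArchive = 2,
                             seed = 41)
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  fmts <- c(ntriples = "nt", turtle = "turtle", rdfxml = "xml")
  for (ours in names(fmts))
    expect_identical(rdflib_triple_count(serializeGraph(g, ours), fmts[[ours]]),
                     nTriples(g), info = ours)
  px <- roadmapPrefixes()
  q <- paste0(paste0("PREFIX ", names(px), ": <", px, ">", collapse = "\n"),
              "\nSELECT ?d ?p WHERE {",
              " ?f rdf:type tcga:File .",
              " ?f tcga:diseaseStudy ?ds . ?ds rdfs:label ?d .",
              " ?f tcga:platform ?pl . ?pl rdfs:label ?p }")
  theirs <- rdflib_select(serializeGraph(g, "turtle"), "turtle", q)
  ours <- result_rows(unique(queryGraph(g, q)))
  expect_identical(sort(unique(theirs)), ours)
})
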