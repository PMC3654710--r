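## ---- dashboard statistics -------------------------------------------

#' Cumulative growth of the file catalogue
#'
#' Counts `File` resources grouped by the UTC calendar day of their
#' first-seen date (or, alternatively, their upstream last-modified
#' date, which extends the series into the repository's pre-scrape
#' history) and accumulates.  Removing files upstream never decreases
#' the series: growth counts when files appeared, not whether they are
#' still present.
#'
#' @param graph A non-empty `RoadmapGraph`.
#' @param by `"first_seen"` (default) or `"last_modified"`.
#' @return `data.frame` with columns `date` (`Date`, strictly
#'   increasing) and `count` (cumulative, non-decreasing).
#' @export
growthSeries <- function(graph, by = c("first_seen", "last_modified")) {
  by <- match.arg(by)
  files <- graphRecords(graph, kinds = "File")
  if (!nrow(files)) stop("graph contains no File resources", call. = FALSE)
  when <- if (by == "first_seen") files$firstSeen else files$lastModified
  day <- as.Date(format(when, "%Y-%m-%d", tz = "UTC"))
  tab <- aggregate(list(n = day), by = list(date = day), FUN = length)
  tab <- tab[order(tab$date), , drop = FALSE]
  data.frame(date = tab$date, count = cumsum(tab$n))
}

#' Estimate the doubling time of a growth series
#'
#' Ordinary least-squares fit of `log2(count)` against time in days;
#' the doubling time is the reciprocal of the slope.  Exactly recovers
#' the doubling period of noiseless exponential growth, and degrades
#' gracefully under multiplicative noise.  A flat or shrinking series
#' has no doubling time and raises a `roadmapr_no_growth` error.
#'
#' @param series A growth series: `data.frame` with `date` (or numeric
#'   `day`) and `count` columns, e.g. from [growthSeries()].
#' @return Doubling time in days.
#' @export
doublingTime <- function(series) {
  count <- series$count
  day <- if (!is.null(series$day)) as.numeric(series$day)
    else as.numeric(series$date - series$date[1])
  ok <- count > 0
  if (sum(ok) < 2)
    stop("need at least two points with positive counts", call. = FALSE)
  fit <- lm(log2(count[ok]) ~ day[ok])
  slope <- unname(coef(fit)[2])
  ## a numerically flat fit (constant series) has no doubling time either
  if (!is.finite(slope) || slope <= .Machine$double.eps^0.5)
    stop(structure(class = c("roadmapr_no_growth", "error", "condition"),
                   list(message = "series does not grow: no doubling time",
                        call = NULL)))
  1 / slope
}

#' Disease-by-platform incidence
#'
#' The bipartite structure behind the dashboard's connection diagram:
#' an edge (disease, platform) exists iff at least one `File` links
#' both a `DiseaseStudy` labelled with the disease code and a
#' `Platform` labelled with the platform name.  Nodes are identified by
#' label, not UUID (labels are what the dashboard displays; kinds
#' partition the label sets, so no collisions arise).
#'
#' Two independent computation paths are available: a direct scan of
#' the graph's records and link triples, and the SPARQL query of
#' [incidenceQuery()]; `method = "both"` runs the two and verifies they
#' agree before returning.
#'
#' @param graph A `RoadmapGraph`.
#' @param method `"index"`, `"sparql"` or `"both"` (default `"index"`).
#' @return List with `diseases` (character), `platforms` (character)
#'   and `edges` (`data.frame` with columns `disease`, `platform`,
#'   sorted).
#' @export
platformDiseaseIncidence <- function(graph,
                                     method = c("index", "sparql", "both")) {
  method <- match.arg(method)
  direct <- function() {
    tr <- graph@triples
    labels <- setNames(tr$o[tr$p == "rdfs:label"], tr$s[tr$p == "rdfs:label"])
    dlink <- tr[tr$p == "tcga:diseaseStudy", c("s", "o")]
    plink <- tr[tr$p == "tcga:platform", c("s", "o")]
    m <- merge(dlink, plink, by = "s")
    edges <- unique(data.frame(disease = unname(labels[m$o.x]),
                               platform = unname(labels[m$o.y]),
                               stringsAsFactors = FALSE))
    edges
  }
  via_sparql <- function() {
    res <- queryGraph(graph, incidenceQuery())
    data.frame(disease = res$disease, platform = res$platform,
               stringsAsFactors = FALSE)
  }
  edges <- switch(method,
    index = direct(),
    sparql = via_sparql(),
    both = {
      a <- .sort_edges(direct())
      b <- .sort_edges(via_sparql())
      if (!identical(a, b))
        stop("incidence mismatch between SPARQL and direct computation",
             call. = FALSE)
      a
    })
  edges <- .sort_edges(edges)
  list(diseases = unique(edges$disease), platforms = unique(edges$platform),
       edges = edges)
}

.sort_edges <- function(edges) {
  edges <- unique(edges)
  edges <- edges[order(edges$disease, edges$platform, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @rdname platformDiseaseIncidence
#' @export
incidenceQuery <- function() {
  paste(
    "SELECT DISTINCT ?disease ?platform WHERE {",
    "  ?f rdf:type tcga:File .",
    "  ?f tcga:diseaseStudy ?d .",
    "  ?d rdfs:label ?disease .",
    "  ?f tcga:platform ?p .",
    "  ?p rdfs:label ?platform .",
    "}", sep = "\n")
}

#' Resource counts per kind
#'
#' Summary-card numbers for the dashboard: how many subjects of each of
#' the seven kinds the graph holds.
#'
#' @param graph A `RoadmapGraph`.
#' @return Named integer vector over [resourceKinds()].
#' @export
countByKind <- function(graph) {
  vapply(setNames(.kinds, .kinds),
         function(k) length(graph@kindIndex[[k]] %||% character()), 0L)
}
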