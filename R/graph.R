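## ---- RoadmapGraph ----------------------------------------------------

setClass("RoadmapGraph",
  representation(
    triples = "data.frame",
    urlIndex = "character",   # normalized url -> uuid
    kindIndex = "list",       # kind -> character vector of uuids
    prefixes = "character"
  )
)

setValidity("RoadmapGraph", function(object) {
  tr <- object@triples
  msgs <- character()
  if (!identical(names(tr), c("s", "p", "o", "ot")))
    msgs <- c(msgs, "triples must have columns s, p, o, ot")
  else {
    bad_ot <- setdiff(unique(tr$ot), c("iri", "string", "anyURI", "dateTime"))
    if (length(bad_ot))
      msgs <- c(msgs, paste("unknown object types:", paste(bad_ot, collapse = ", ")))
    single <- tr[tr$p %in% .record_predicates, c("s", "p")]
    if (anyDuplicated(single))
      msgs <- c(msgs, "duplicate (subject, predicate) for a single-valued predicate")
  }
  if (!all(c("tcga", "rdf", "rdfs", "xsd") %in% names(object@prefixes)))
    msgs <- c(msgs, "prefix table must bind tcga, rdf, rdfs and xsd")
  if (length(msgs)) msgs else TRUE
})

#' Create an empty road-map graph
#'
#' The graph holds every RDF triple describing resources ever seen,
#' together with two derived indexes: normalized URL to UUID, and kind
#' to the set of UUIDs of that kind.  Both indexes are always
#' rederivable from the triples themselves.
#'
#' @param base Base IRI for the `tcga:` prefix.
#' @return A `RoadmapGraph` object.
#' @export
#' @examples
#' g <- roadmapGraph()
#' countByKind(g)
roadmapGraph <- function(base = .default_base_iri) {
  new("RoadmapGraph", triples = .triple_frame(),
      urlIndex = setNames(character(), character()),
      kindIndex = setNames(vector("list", length(.kinds)), .kinds),
      prefixes = roadmapPrefixes(base))
}

#' Graph accessors
#'
#' @param graph A `RoadmapGraph`.
#' @return `graphTriples`: the triple table; `nTriples`: triple count;
#'   `knownURLs`: named character of normalized URL to UUID;
#'   `uuidsOfKind`: character vector of UUIDs of one kind.
#' @name graph-accessors
#' @export
graphTriples <- function(graph) graph@triples

#' @rdname graph-accessors
#' @export
nTriples <- function(graph) nrow(graph@triples)

#' @rdname graph-accessors
#' @export
knownURLs <- function(graph) graph@urlIndex

#' @rdname graph-accessors
#' @param kind A kind name from [resourceKinds()].
#' @export
uuidsOfKind <- function(graph, kind) {
  kind <- match.arg(kind, .kinds)
  graph@kindIndex[[kind]] %||% character()
}

setMethod("show", "RoadmapGraph", function(object) {
  cat("RoadmapGraph with", nrow(object@triples), "triples\n")
  counts <- countByKind(object)
  counts <- counts[counts > 0]
  if (length(counts))
    cat(paste0("  ", format(names(counts), width = 13), " ", counts,
               collapse = "\n"), "\n")
  invisible(object)
})

#' Rebuild the derived indexes from the triples
#'
#' Used by the consistency audit: the stored `urlIndex` and `kindIndex`
#' must equal the ones recomputed here from scratch.
#'
#' @param triples Triple table.
#' @return List with elements `urlIndex` and `kindIndex`.
#' @export
rebuildIndexes <- function(triples) {
  urls <- triples[triples$p == "tcga:url", , drop = FALSE]
  urlIndex <- setNames(sub("^tcga:", "", urls$s),
                       vapply(urls$o, normalizeURL, ""))
  urlIndex <- urlIndex[order(names(urlIndex), method = "radix")]
  types <- triples[triples$p == "rdf:type", , drop = FALSE]
  kindIndex <- setNames(vector("list", length(.kinds)), .kinds)
  for (k in .kinds) {
    u <- sub("^tcga:", "", types$s[types$o == kindClass(k)])
    kindIndex[[k]] <- sort(u, method = "radix")
  }
  list(urlIndex = urlIndex, kindIndex = kindIndex)
}

.sorted_graph_indexes <- function(graph) {
  list(
    urlIndex = graph@urlIndex[order(names(graph@urlIndex), method = "radix")],
    kindIndex = lapply(graph@kindIndex, function(u)
      sort(u %||% character(), method = "radix"))
  )
}

#' Insert or update one resource in the graph
#'
#' If the record's normalized URL is unknown, all its triples are
#' inserted.  If it is known, only the `tcga:lastSeen` and
#' `tcga:lastModified` literals are replaced: the UUID, `firstSeen`,
#' label, type and ancestor links of a known resource are never touched,
#' so `firstSeen` is write-once and identity is stable across scrapes.
#' Attempting to change the kind of a known URL raises a
#' `roadmapr_kind_conflict` error.
#'
#' @param graph A `RoadmapGraph`.
#' @param record A valid `ResourceRecord`.
#' @return The updated graph.
#' @export
upsertResource <- function(graph, record) {
  validObject(record)
  key <- normalizeURL(record@url)
  known <- graph@urlIndex[key]
  if (is.na(known)) {
    graph@triples <- rbind(graph@triples, resourceToTriples(record))
    graph@urlIndex[key] <- record@uuid
    graph@kindIndex[[record@kind]] <- c(graph@kindIndex[[record@kind]],
                                        record@uuid)
    return(graph)
  }
  subj <- paste0("tcga:", unname(known))
  stored_kind <- graph@triples$o[graph@triples$s == subj &
                                 graph@triples$p == "rdf:type"]
  if (!identical(stored_kind, kindClass(record@kind)))
    stop(structure(class = c("roadmapr_kind_conflict", "error", "condition"),
                   list(message = paste0(
                     "resource ", record@url, " is already recorded as ",
                     stored_kind, "; refusing to re-type it as ",
                     kindClass(record@kind)),
                     call = NULL)))
  i_seen <- which(graph@triples$s == subj & graph@triples$p == "tcga:lastSeen")
  i_mod <- which(graph@triples$s == subj &
                 graph@triples$p == "tcga:lastModified")
  graph@triples$o[i_seen] <- formatDateTime(record@lastSeen)
  graph@triples$o[i_mod] <- formatDateTime(record@lastModified)
  graph
}

#' Audit the structural invariants of a graph
#'
#' Checks that (i) every subject has exactly one `rdf:type`,
#' `rdfs:label`, `tcga:url`, `tcga:firstSeen`, `tcga:lastSeen` and
#' `tcga:lastModified`; (ii) every link triple on a `tcga:File` subject
#' points at a subject of the matching class; and (iii) the stored URL
#' and kind indexes equal the ones rebuilt from the triples.
#'
#' @param graph A `RoadmapGraph`.
#' @return `TRUE` invisibly; stops with a description on violation.
#' @export
auditGraph <- function(graph) {
  tr <- graph@triples
  subjects <- unique(tr$s)
  for (p in .record_predicates) {
    n <- table(factor(tr$s[tr$p == p], levels = subjects))
    if (any(n != 1))
      stop("cardinality violation: ", sum(n != 1), " subjects do not have ",
           "exactly one ", p, call. = FALSE)
  }
  lp <- .link_properties()
  types <- setNames(tr$o[tr$p == "rdf:type"], tr$s[tr$p == "rdf:type"])
  links <- tr[tr$p %in% lp, , drop = FALSE]
  if (nrow(links)) {
    if (!all(types[links$s] == "tcga:File"))
      stop("referential violation: link triple on a non-File subject",
           call. = FALSE)
    want <- kindClass(names(lp)[match(links$p, lp)])
    if (!all(types[links$o] == want))
      stop("referential violation: link target of the wrong class",
           call. = FALSE)
  }
  rebuilt <- rebuildIndexes(tr)
  if (!identical(rebuilt, .sorted_graph_indexes(graph)))
    stop("index drift: stored indexes differ from rebuild", call. = FALSE)
  invisible(TRUE)
}

## ---- record tables ---------------------------------------------------

#' Tabulate the resource records held in a graph
#'
#' Reshapes the graph into one row per subject with the six record
#' properties as columns.  This is the direct (non-SPARQL) access path
#' used by the temporal queries and the dashboard statistics.
#'
#' @param graph A `RoadmapGraph`.
#' @param kinds Restrict to these kinds (default: all).
#' @return `data.frame` with columns `uuid`, `kind`, `label`, `url`,
#'   `firstSeen`, `lastSeen`, `lastModified` (dates are UTC `POSIXct`).
#' @export
graphRecords <- function(graph, kinds = NULL) {
  tr <- graph@triples
  subjects <- unique(tr$s)
  col <- function(p) {
    rows <- tr[tr$p == p, , drop = FALSE]
    rows$o[match(subjects, rows$s)]
  }
  out <- data.frame(
    uuid = sub("^tcga:", "", subjects),
    kind = sub("^tcga:", "", col("rdf:type")),
    label = col("rdfs:label"),
    url = col("tcga:url"),
    firstSeen = parseDateTime(col("tcga:firstSeen")),
    lastSeen = parseDateTime(col("tcga:lastSeen")),
    lastModified = parseDateTime(col("tcga:lastModified")),
    stringsAsFactors = FALSE
  )
  if (!is.null(kinds)) out <- out[out$kind %in% kinds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconstruct full resource records (with links) from the graph
#'
#' @param graph A `RoadmapGraph`.
#' @param uuids UUIDs to reconstruct.
#' @return List of `ResourceRecord` objects.
#' @export
recordsFromGraph <- function(graph, uuids) {
  subjects <- paste0("tcga:", uuids)
  tr <- graph@triples[graph@triples$s %in% subjects, , drop = FALSE]
  lapply(subjects, function(s) recordFromTriples(tr, s))
}
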