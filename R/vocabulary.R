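#' @import methods
#' @importFrom stats aggregate coef lm runif setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Namespace prefixes used throughout the graph.  Terms are stored in
## prefixed form ("tcga:gbm-uuid", "rdf:type"); serializers expand them.
.default_base_iri <- "http://example.org/tcga#"

#' Namespace prefix table
#'
#' The closed set of namespace prefixes used by the road-map vocabulary:
#' `tcga:` (configurable base IRI), `rdf:`, `rdfs:` and `xsd:`.
#'
#' @param base Base IRI bound to the `tcga:` prefix.
#' @return Named character vector mapping prefix to IRI.
#' @export
#' @examples
#' roadmapPrefixes()
roadmapPrefixes <- function(base = .default_base_iri) {
  c(
    tcga = base,
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd  = "http://www.w3.org/2001/XMLSchema#"
  )
}

## The seven resource kinds, ordered by directory depth 1..6 plus File.
.kinds <- c("DiseaseStudy", "CenterType", "CenterDomain", "Platform",
            "DataType", "Archive", "File")

#' Resource kinds of the repository schema
#'
#' Exactly seven kinds exist, the first six corresponding in order to
#' directory depths 1 through 6 below the repository root; everything
#' deeper that is not a directory is a `File`.
#'
#' @return Character vector of the seven kind names.
#' @export
resourceKinds <- function() .kinds

#' Class and link-property identifiers of a kind
#'
#' Each kind has a class identifier `tcga:<Name>`; the six non-File
#' kinds additionally have a link property obtained by lower-casing the
#' first letter of the class name (`tcga:diseaseStudy`, ...,
#' `tcga:archive`), used on `tcga:File` subjects to point at their
#' ancestors.
#'
#' @param kind A kind name from [resourceKinds()].
#' @return Prefixed identifier string.
#' @export
kindClass <- function(kind) {
  kind <- match.arg(kind, .kinds, several.ok = TRUE)
  paste0("tcga:", kind)
}

#' @rdname kindClass
#' @export
kindLinkProperty <- function(kind) {
  kind <- match.arg(kind, .kinds[.kinds != "File"], several.ok = TRUE)
  paste0("tcga:", tolower(substr(kind, 1, 1)), substr(kind, 2, nchar(kind)))
}

.link_properties <- function() {
  setNames(vapply(.kinds[1:6], kindLinkProperty, ""), .kinds[1:6])
}

## Closed predicate vocabulary (single-valued, one per subject).
.record_predicates <- c("rdf:type", "rdfs:label", "tcga:url",
                        "tcga:firstSeen", "tcga:lastSeen", "tcga:lastModified")

#' Classify a directory entry by its depth below the repository root
#'
#' The repository root is depth 0.  Directories at depths 1..6 map, in
#' order, to `DiseaseStudy`, `CenterType`, `CenterDomain`, `Platform`,
#' `DataType` and `Archive`.  Any non-directory at depth >= 2 is a
#' `File`.  Directories deeper than 6 carry no kind (`NA`): they are
#' untyped containers that are still traversed, and files below them
#' link to the depth-6 `Archive` ancestor.
#'
#' @param depth Integer depth >= 1 (root itself is 0 and not classifiable).
#' @param isDirectory Logical flag.
#' @return A kind name, or `NA_character_` for an untyped deep directory.
#' @export
#' @examples
#' classifyByDepth(1, TRUE)   # "DiseaseStudy"
#' classifyByDepth(4, TRUE)   # "Platform"
#' classifyByDepth(7, FALSE)  # "File"
classifyByDepth <- function(depth, isDirectory) {
  if (length(depth) != 1 || is.na(depth) || depth < 1 || depth != round(depth))
    stop("structure violation: depth must be an integer >= 1 (root is 0)",
         call. = FALSE)
  if (!isDirectory) {
    if (depth < 2)
      stop("structure violation: a non-directory cannot sit at depth 1",
           call. = FALSE)
    return("File")
  }
  if (depth <= 6) .kinds[depth] else NA_character_
}

#' Normalize a URL into its identity key
#'
#' Lower-cases the scheme and host, strips the scheme's default port,
#' strips any trailing slash from the path, and canonicalises
#' percent-encoding (decode, then re-encode each path segment).  The
#' normalized form is the key under which a resource is recognised
#' across scrapes and listing dialects.
#'
#' @param url Absolute URL (or a bare path, normalized the same way).
#' @return Normalized URL string.
#' @export
normalizeURL <- function(url) {
  stopifnot(is.character(url), length(url) == 1)
  if (!nzchar(url)) stop("empty url", call. = FALSE)
  m <- regmatches(url, regexec("^([A-Za-z][A-Za-z0-9+.-]*)://([^/]*)(/.*)?$", url))[[1]]
  if (length(m) == 0) {
    return(.normalize_path(url))
  }
  scheme <- tolower(m[2])
  authority <- tolower(m[3])
  path <- m[4]
  default_port <- c(http = "80", https = "443", ftp = "21")[scheme]
  if (!is.na(default_port))
    authority <- sub(paste0(":", default_port, "$"), "", authority)
  paste0(scheme, "://", authority, .normalize_path(path))
}

.normalize_path <- function(path) {
  if (is.na(path) || !nzchar(path)) return("")
  path <- sub("/+$", "", path)
  if (!nzchar(path)) return("")
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  segs <- vapply(segs, function(s) {
    if (!nzchar(s)) return(s)
    curl::curl_escape(curl::curl_unescape(s))
  }, "", USE.NAMES = FALSE)
  paste(segs, collapse = "/")
}

## RFC 4122 URL namespace; name-based UUIDs make minting reproducible
## and stateless while the identifier itself stays semantically neutral.
.uuid_namespace <- "6ba7b811-9dad-11d1-80b4-00c04fd430c8"

#' Mint a deterministic, semantically neutral UUID for a resource URL
#'
#' Computes an RFC 4122 version-5 (name-based, SHA-1) UUID from a fixed
#' namespace and the normalized URL.  The same URL always yields the
#' same UUID, so re-scrapes recognise a known resource without any
#' stored state, while the UUID itself exposes no repository semantics:
#' it is a "cool URI" that never changes even as listings move or get
#' re-rendered.
#'
#' @param url Resource URL (normalized internally with [normalizeURL()]).
#' @return UUID string.
#' @export
#' @examples
#' mintUUID("http://example.org/tcga/gbm/") == mintUUID("http://example.org/tcga/gbm")
mintUUID <- function(url) {
  if (!is.character(url) || length(url) != 1 || !nzchar(url))
    stop("empty url", call. = FALSE)
  uuid::UUIDfromName(.uuid_namespace, normalizeURL(url), type = "sha1")
}

#' Human-readable label of a resource URL
#'
#' The final path segment of the URL, with any trailing slash removed
#' and percent-encoding decoded.
#'
#' @param url Absolute URL.
#' @return Label string.
#' @export
labelFromURL <- function(url) {
  stopifnot(is.character(url), length(url) == 1, nzchar(url))
  path <- sub("^[A-Za-z][A-Za-z0-9+.-]*://[^/]*", "", url)
  path <- sub("[?#].*$", "", path)
  path <- sub("/+$", "", path)
  if (!nzchar(path) || path == "/")
    stop("url with empty path has no label", call. = FALSE)
  seg <- tail(strsplit(path, "/", fixed = TRUE)[[1]], 1)
  if (!nzchar(seg)) stop("url with empty path has no label", call. = FALSE)
  curl::curl_unescape(seg)
}

## ---- ResourceRecord -------------------------------------------------

setClass("ResourceRecord",
  representation(
    uuid = "character",
    kind = "character",
    label = "character",
    url = "character",
    firstSeen = "POSIXct",
    lastSeen = "POSIXct",
    lastModified = "POSIXct",
    links = "character"
  )
)

setValidity("ResourceRecord", function(object) {
  msgs <- character()
  for (s in c("uuid", "kind", "label", "url"))
    if (length(slot(object, s)) != 1 || is.na(slot(object, s)) ||
        !nzchar(slot(object, s)))
      msgs <- c(msgs, paste0("'", s, "' must be a single non-empty string"))
  for (s in c("firstSeen", "lastSeen", "lastModified"))
    if (length(slot(object, s)) != 1 || is.na(slot(object, s)))
      msgs <- c(msgs, paste0("'", s, "' must be a single timestamp"))
  if (!length(msgs)) {
    if (!object@kind %in% .kinds)
      msgs <- c(msgs, "unknown resource kind")
    if (object@lastSeen < object@firstSeen)
      msgs <- c(msgs, "lastSeen must be >= firstSeen")
    if (object@kind != "File" && length(object@links))
      msgs <- c(msgs, "only File records carry ancestor links")
    if (length(object@links)) {
      bad <- setdiff(names(object@links), .kinds[1:6])
      if (length(bad) || is.null(names(object@links)))
        msgs <- c(msgs, "links must be named by non-File kinds")
      if (anyDuplicated(names(object@links)))
        msgs <- c(msgs, "at most one link per ancestor kind")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a resource record
#'
#' One repository entity (file or folder) with its kind, label, URL,
#' deterministic UUID and the three provenance dates.  `File` records
#' additionally carry `links`: a named character vector mapping each
#' ancestor kind present on the file's path (up to six) to that
#' ancestor's UUID.
#'
#' @param url Absolute URL of the resource.
#' @param kind A kind name from [resourceKinds()].
#' @param firstSeen,lastSeen,lastModified `POSIXct` timestamps (UTC).
#' @param label Human-readable name; defaults to [labelFromURL()].
#' @param uuid Identifier; defaults to [mintUUID()] of `url`.
#' @param links Named character vector of ancestor UUIDs (File only).
#' @return A `ResourceRecord` object.
#' @export
resourceRecord <- function(url, kind, firstSeen, lastSeen = firstSeen,
                           lastModified = firstSeen,
                           label = labelFromURL(url),
                           uuid = mintUUID(url),
                           links = character()) {
  new("ResourceRecord", uuid = uuid, kind = kind, label = label, url = url,
      firstSeen = .as_utc(firstSeen), lastSeen = .as_utc(lastSeen),
      lastModified = .as_utc(lastModified), links = links)
}

#' Accessors for resource records
#'
#' @param record A `ResourceRecord`.
#' @return The requested slot: a string, a named character vector of
#'   ancestor UUIDs, or a named `POSIXct` of the three provenance dates.
#' @name record-accessors
#' @export
recordUUID <- function(record) record@uuid

#' @rdname record-accessors
#' @export
recordKind <- function(record) record@kind

#' @rdname record-accessors
#' @export
recordLabel <- function(record) record@label

#' @rdname record-accessors
#' @export
recordURL <- function(record) record@url

#' @rdname record-accessors
#' @export
recordLinks <- function(record) record@links

#' @rdname record-accessors
#' @export
recordDates <- function(record) {
  c(firstSeen = record@firstSeen, lastSeen = record@lastSeen,
    lastModified = record@lastModified)
}

setMethod("show", "ResourceRecord", function(object) {
  cat("ResourceRecord <tcga:", object@uuid, ">\n", sep = "")
  cat("  kind:  ", object@kind, "\n", sep = "")
  cat("  label: ", object@label, "\n", sep = "")
  cat("  url:   ", object@url, "\n", sep = "")
  cat("  seen:  ", formatDateTime(object@firstSeen), " .. ",
      formatDateTime(object@lastSeen),
      "  (modified ", formatDateTime(object@lastModified), ")\n", sep = "")
  if (length(object@links))
    cat("  links: ", paste0(names(object@links), collapse = ", "), "\n",
        sep = "")
  invisible(object)
})

.as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

#' Format / parse UTC date-time literals
#'
#' All date literals in the graph are `xsd:dateTime` in UTC with a `Z`
#' suffix; listing dates without a timezone are assumed UTC.
#'
#' @param x `POSIXct` for formatting; string for parsing.
#' @return ISO-8601 string, or `POSIXct` (UTC).
#' @export
formatDateTime <- function(x) {
  format(.as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' @rdname formatDateTime
#' @export
parseDateTime <- function(x) {
  as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

## ---- record <-> triples ---------------------------------------------

.triple_frame <- function(s = character(), p = character(), o = character(),
                          ot = character()) {
  data.frame(s = s, p = p, o = o, ot = ot, stringsAsFactors = FALSE)
}

#' Convert a resource record to RDF triples
#'
#' Emits exactly one `rdf:type`, one `rdfs:label`, one `tcga:url` and
#' one each of `tcga:firstSeen`, `tcga:lastSeen` and `tcga:lastModified`
#' for the subject `tcga:<uuid>`, plus — for `File` records — one link
#' triple per ancestor (`tcga:diseaseStudy`, `tcga:centerType`,
#' `tcga:centerDomain`, `tcga:platform`, `tcga:dataType`,
#' `tcga:archive`).  A non-File record therefore yields 6 triples and a
#' File with k linked ancestors 6 + k.
#'
#' @param record A valid `ResourceRecord`.
#' @return Triple table (columns `s`, `p`, `o`, `ot`).
#' @export
resourceToTriples <- function(record) {
  validObject(record)
  subj <- paste0("tcga:", record@uuid)
  tr <- .triple_frame(
    s = rep(subj, 6),
    p = .record_predicates,
    o = c(kindClass(record@kind), record@label, record@url,
          formatDateTime(record@firstSeen), formatDateTime(record@lastSeen),
          formatDateTime(record@lastModified)),
    ot = c("iri", "string", "anyURI", "dateTime", "dateTime", "dateTime")
  )
  if (length(record@links)) {
    lp <- .link_properties()
    tr <- rbind(tr, .triple_frame(
      s = rep(subj, length(record@links)),
      p = unname(lp[names(record@links)]),
      o = paste0("tcga:", unname(record@links)),
      ot = rep("iri", length(record@links))
    ))
  }
  tr
}

#' Rebuild a resource record from its triples
#'
#' Inverse of [resourceToTriples()]: given the triples of one subject,
#' reconstructs the identical `ResourceRecord` (round-trip losslessness
#' is a schema invariant).
#'
#' @param triples Triple table containing the subject's triples.
#' @param subject Subject identifier `tcga:<uuid>`; defaults to the only
#'   subject present.
#' @return A `ResourceRecord`.
#' @export
recordFromTriples <- function(triples, subject = NULL) {
  if (is.null(subject)) {
    subject <- unique(triples$s)
    if (length(subject) != 1)
      stop("triples contain ", length(subject),
           " subjects; pass `subject`", call. = FALSE)
  }
  tr <- triples[triples$s == subject, , drop = FALSE]
  getv <- function(p) {
    v <- tr$o[tr$p == p]
    if (length(v) != 1)
      stop("subject ", subject, " has ", length(v), " values for ", p,
           call. = FALSE)
    v
  }
  kind <- sub("^tcga:", "", getv("rdf:type"))
  lp <- .link_properties()
  link_rows <- tr[tr$p %in% lp, , drop = FALSE]
  links <- character()
  if (nrow(link_rows)) {
    links <- sub("^tcga:", "", link_rows$o)
    names(links) <- names(lp)[match(link_rows$p, lp)]
  }
  resourceRecord(
    url = getv("tcga:url"), kind = kind, label = getv("rdfs:label"),
    uuid = sub("^tcga:", "", subject),
    firstSeen = parseDateTime(getv("tcga:firstSeen")),
    lastSeen = parseDateTime(getv("tcga:lastSeen")),
    lastModified = parseDateTime(getv("tcga:lastModified")),
    links = links
  )
}

#' Export the vocabulary as a small Turtle ontology
#'
#' Writes the seven classes and the closed property vocabulary as
#' Turtle, for use by external SPARQL tooling.
#'
#' @param file Path to write to, or `NULL` to return the text.
#' @param base Base IRI for the `tcga:` prefix.
#' @return The Turtle text, invisibly when written to a file.
#' @export
writeOntology <- function(file = NULL, base = .default_base_iri) {
  px <- roadmapPrefixes(base)
  lines <- c(
    paste0("@prefix ", names(px), ": <", px, "> ."),
    "",
    paste0("tcga:", .kinds, " a rdfs:Class ."),
    "",
    "tcga:url a rdf:Property ; rdfs:range xsd:anyURI .",
    "tcga:firstSeen a rdf:Property ; rdfs:range xsd:dateTime .",
    "tcga:lastSeen a rdf:Property ; rdfs:range xsd:dateTime .",
    "tcga:lastModified a rdf:Property ; rdfs:range xsd:dateTime .",
    paste0(unname(.link_properties()), " a rdf:Property ; rdfs:range ",
           "tcga:", .kinds[1:6], " ; rdfs:domain tcga:File .")
  )
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
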