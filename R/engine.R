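## ---- ScrapeReport ----------------------------------------------------

setClass("ScrapeReport",
  representation(
    scrapeTime = "POSIXct",
    added = "integer",
    updated = "integer",
    errors = "integer",
    perKindCounts = "integer"
  )
)

setValidity("ScrapeReport", function(object) {
  if (object@added + object@updated != sum(object@perKindCounts))
    "added + updated must equal the total of perKindCounts"
  else TRUE
})

setMethod("show", "ScrapeReport", function(object) {
  cat("ScrapeReport @ ", formatDateTime(object@scrapeTime), "\n",
      "  added: ", object@added, "  updated: ", object@updated,
      "  errors: ", object@errors, "\n", sep = "")
  counts <- object@perKindCounts[object@perKindCounts > 0]
  if (length(counts))
    cat(paste0("  ", format(names(counts), width = 13), " ", counts,
               collapse = "\n"), "\n")
  invisible(object)
})

#' @rdname updateRoadmap
#' @param report A `ScrapeReport`.
#' @export
reportCounts <- function(report) {
  c(added = report@added, updated = report@updated, errors = report@errors)
}

#' @rdname updateRoadmap
#' @export
reportPerKind <- function(report) report@perKindCounts

## ---- incremental scrape ---------------------------------------------

#' Scrape a repository into the road map (incremental update)
#'
#' Walks the source depth-first and processes every entry: if its
#' normalized URL is already known to the graph, only the resource's
#' last-seen date is advanced to `scrapeTime` and its last-modified
#' date refreshed from the listing; if unknown, a new deterministic
#' UUID and the full triple set are generated with
#' `firstSeen = lastSeen = scrapeTime`.  File entries additionally get
#' one link triple per typed ancestor on their path (directories deeper
#' than the Archive level are traversed but untyped, and files below
#' them link to the depth-6 Archive).  Resources absent from the crawl
#' are left untouched — their stale last-seen date is what later
#' identifies removals.
#'
#' `scrapeTime` is fixed once at crawl start and stamped on every entry
#' of the crawl, so "the latest last-seen date" is a well-defined
#' equivalence class; rerunning with the same `scrapeTime` is
#' idempotent.
#'
#' @param graph A `RoadmapGraph`.
#' @param source A [crawlSource()].
#' @param scrapeTime `POSIXct` timestamp of this scrape (default: now,
#'   UTC).
#' @return List with elements `graph` (updated) and `report`
#'   (a `ScrapeReport`).
#' @export
updateRoadmap <- function(graph, source, scrapeTime = Sys.time()) {
  scrapeTime <- .as_utc(scrapeTime)
  entries <- walkSource(source)
  root_url <- if (source@mode == "http") sub("/*$", "", source@root)
    else paste0("file://", sub("/*$", "", normalizePath(source@root)))
  if (source@mode == "index_file")
    root_url <- paste0("file://", dirname(normalizePath(source@root)))
  added <- 0L
  updated <- 0L
  errors <- 0L
  per_kind <- setNames(integer(length(.kinds)), .kinds)
  seen_now <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(entries))) {
    if (entries$status[i] != "ok") { errors <- errors + 1L; next }
    depth <- entries$depth[i]
    kind <- tryCatch(classifyByDepth(depth, entries$isDirectory[i]),
                     error = function(e) NA_character_)
    if (is.na(kind)) next   # untyped deep container (or structure oddity)
    url <- entries$url[i]
    key <- normalizeURL(url)
    if (!is.null(seen_now[[key]])) next
    seen_now[[key]] <- TRUE
    links <- character()
    if (kind == "File") {
      anc <- .ancestor_urls(url, root_url)
      k <- min(length(anc), 6L)
      if (k > 0) {
        links <- vapply(anc[seq_len(k)], mintUUID, "")
        names(links) <- .kinds[seq_len(k)]
      }
    }
    mod <- entries$modified[i]
    if (is.na(mod)) mod <- scrapeTime
    rec <- resourceRecord(url = url, kind = kind,
                          firstSeen = scrapeTime, lastSeen = scrapeTime,
                          lastModified = mod, links = links)
    was_known <- !is.na(graph@urlIndex[key])
    graph <- upsertResource(graph, rec)
    if (was_known) updated <- updated + 1L else added <- added + 1L
    per_kind[kind] <- per_kind[kind] + 1L
  }
  report <- new("ScrapeReport", scrapeTime = scrapeTime, added = added,
                updated = updated, errors = errors, perKindCounts = per_kind)
  list(graph = graph, report = report)
}

## ancestor URLs of a file URL, relative to the repository root,
## ordered outermost (depth 1) first
.ancestor_urls <- function(url, root_url) {
  root_n <- normalizeURL(root_url)
  url_n <- normalizeURL(url)
  if (!startsWith(url_n, paste0(root_n, "/"))) return(character())
  rel <- substring(url_n, nchar(root_n) + 2)
  segs <- strsplit(rel, "/", fixed = TRUE)[[1]]
  if (length(segs) < 2) return(character())
  vapply(seq_len(length(segs) - 1L), function(d)
    paste0(root_n, "/", paste(segs[seq_len(d)], collapse = "/")), "")
}

## ---- temporal queries ------------------------------------------------

#' Detect resources removed from the repository
#'
#' A resource that has been removed upstream keeps its triples in the
#' graph but stops being re-stamped: its last-seen date stays behind.
#' This returns every resource whose last-seen date is earlier than
#' `asOf` (defaulting to the latest last-seen date in the whole graph),
#' i.e. everything that existed at some point but was not present
#' during the most recent scrape.
#'
#' @param graph A non-empty `RoadmapGraph`.
#' @param asOf Reference timestamp; default: the maximum last-seen date.
#' @return Record table (see [graphRecords()]) of the removed
#'   resources, all kinds included (a removed folder is reported along
#'   with all its descendants).
#' @export
detectRemoved <- function(graph, asOf = NULL) {
  recs <- graphRecords(graph)
  if (!nrow(recs)) stop("empty graph: no scrape has been recorded",
                        call. = FALSE)
  if (is.null(asOf)) asOf <- max(recs$lastSeen)
  out <- recs[recs$lastSeen < .as_utc(asOf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve the file set as of a date
#'
#' Reproducibility query: which files would an analysis run at time `t`
#' have had available?  In `"first_seen"` mode a file counts as present
#' at `t` when it had already been seen (`firstSeen <= t`) and had not
#' yet dropped out of the scrapes (`lastSeen >= t`) — presence is known
#' at scrape granularity.  In `"last_modified"` mode files with
#' `lastModified <= t` are returned, which reconstructs repository
#' states predating the first scrape from the upstream modification
#' dates.
#'
#' @param graph A `RoadmapGraph`.
#' @param t Timestamp of interest.
#' @param mode `"first_seen"` (default) or `"last_modified"`.
#' @return Record table of the matching `File` resources.
#' @export
resolveAsOf <- function(graph, t, mode = c("first_seen", "last_modified")) {
  mode <- match.arg(mode)
  t <- .as_utc(t)
  files <- graphRecords(graph, kinds = "File")
  out <- if (mode == "first_seen")
    files[files$firstSeen <= t & files$lastSeen >= t, , drop = FALSE]
  else
    files[files$lastModified <= t, , drop = FALSE]
  rownames(out) <- NULL
  out
}
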