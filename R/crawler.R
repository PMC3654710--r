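## ---- CrawlSource -----------------------------------------------------

setClass("CrawlSource",
  representation(
    mode = "character",
    root = "character",
    politenessDelay = "numeric",
    maxRetries = "integer",
    timeout = "numeric",
    dialect = "character",
    transport = "ANY"          # function(url) -> list(status, content), or NULL
  )
)

setValidity("CrawlSource", function(object) {
  msgs <- character()
  if (!object@mode %in% c("http", "local", "index_file"))
    msgs <- c(msgs, "mode must be http, local or index_file")
  if (length(object@root) != 1 || !nzchar(object@root))
    msgs <- c(msgs, "root must be a single non-empty URL or path")
  if (object@mode %in% c("local", "index_file") && !file.exists(object@root))
    msgs <- c(msgs, paste0("root not resolvable: ", object@root))
  if (object@politenessDelay < 0) msgs <- c(msgs, "politenessDelay must be >= 0")
  if (!is.null(object@transport) && !is.function(object@transport))
    msgs <- c(msgs, "transport must be NULL or a function(url)")
  if (length(msgs)) msgs else TRUE
})

#' Describe a crawl target
#'
#' A crawl source is either a live HTTP site serving directory-index
#' pages, a local directory tree, or a single recursive index file of
#' the `ls -Rl > index.txt` form.  The crawl is single-threaded and
#' honours a politeness delay between HTTP fetches.
#'
#' @param mode One of `"http"`, `"local"`, `"index_file"`.
#' @param root Root URL (http mode) or path (local tree / index file).
#' @param politenessDelay Seconds to wait between HTTP fetches
#'   (default 0.1).
#' @param maxRetries Fetch attempts per URL before an error event.
#' @param timeout Per-fetch timeout in seconds.
#' @param dialect Listing dialect: `"apache"` (table and pre variants),
#'   `"nginx"`, or `"plain"` (bare href scraping).
#' @param transport Optional replacement fetch function
#'   `function(url) -> list(status, content)`; the default uses curl.
#'   Mainly useful for testing crawls without sockets.
#' @return A `CrawlSource` object.
#' @export
crawlSource <- function(mode = c("http", "local", "index_file"), root,
                        politenessDelay = 0.1, maxRetries = 3L,
                        timeout = 10, dialect = "apache",
                        transport = NULL) {
  new("CrawlSource", mode = match.arg(mode), root = root,
      politenessDelay = politenessDelay, maxRetries = as.integer(maxRetries),
      timeout = timeout, dialect = dialect, transport = transport)
}

setMethod("show", "CrawlSource", function(object) {
  cat("CrawlSource [", object@mode, "] ", object@root, "\n", sep = "")
  invisible(object)
})

## ---- listing parsers -------------------------------------------------

## "01-Apr-2012" style month names are mapped through month.abb (always
## English) rather than strptime's %b, which is locale-dependent
.month_names_to_iso <- function(txt) {
  m <- regexec("^([0-9]{2})-([A-Za-z]{3})-([0-9]{4})(.*)$", txt)
  mi <- regmatches(txt, m)[[1]]
  if (!length(mi)) return(txt)
  mon <- match(mi[3], month.abb)
  if (is.na(mon)) return(txt)
  paste0(mi[4], "-", sprintf("%02d", mon), "-", mi[2], mi[5])
}

.parse_listing_date <- function(txt) {
  m <- regmatches(txt, regexpr(
    "([0-9]{4}-[0-9]{2}-[0-9]{2}|[0-9]{2}-[A-Za-z]{3}-[0-9]{4}) [0-9]{2}:[0-9]{2}(:[0-9]{2})?",
    txt))
  if (!length(m)) return(as.POSIXct(NA))
  iso <- .month_names_to_iso(m[1])
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    d <- as.POSIXct(strptime(iso, fmt, tz = "UTC"))
    if (!is.na(d)) return(d)
  }
  as.POSIXct(NA)
}

.parse_listing_size <- function(txt) {
  m <- regmatches(txt, regexpr("(?<![0-9:.-])[0-9]+(\\.[0-9]+)?[KMG]?(?![0-9:-])",
                               txt, perl = TRUE))
  if (!length(m)) return(NA_real_)
  mult <- c(K = 1024, M = 1024^2, G = 1024^3)
  unit <- substr(m[1], nchar(m[1]), nchar(m[1]))
  if (unit %in% names(mult))
    as.numeric(substr(m[1], 1, nchar(m[1]) - 1)) * mult[[unit]]
  else as.numeric(m[1])
}

.entry_frame <- function(name = character(), isDirectory = logical(),
                         modified = as.POSIXct(character(), tz = "UTC"),
                         size = numeric(), url = character()) {
  data.frame(name = name, isDirectory = isDirectory, modified = modified,
             size = size, url = url, stringsAsFactors = FALSE)
}

#' Parse one directory-index page
#'
#' Extracts child entries from an Apache autoindex page (table or
#' `<pre>` variant), an nginx autoindex page, or — as a fallback — any
#' page with scrapable hrefs.  Parent-directory and sort-control links
#' are excluded; a trailing slash on the href marks a directory; the
#' modified-date column is parsed when present (dates without a
#' timezone are taken as UTC).
#'
#' @param html Page content (HTML string).
#' @param baseURL URL of the listing, used to resolve child URLs.
#' @param dialect `"apache"`, `"nginx"` or `"plain"`.
#' @return `data.frame` with columns `name`, `isDirectory`, `modified`,
#'   `size`, `url`, in page order.
#' @export
parseListing <- function(html, baseURL, dialect = c("apache", "nginx", "plain")) {
  dialect <- match.arg(dialect)
  doc <- tryCatch(xml2::read_html(html),
                  error = function(e) NULL)
  if (is.null(doc))
    stop(structure(class = c("roadmapr_parse_error", "error", "condition"),
                   list(message = paste0("unparseable listing at ", baseURL),
                        call = NULL, url = baseURL)))
  anchors <- xml2::xml_find_all(doc, ".//a[@href]")
  rows <- lapply(anchors, function(a) {
    href <- xml2::xml_attr(a, "href")
    if (grepl("^(\\?|#|mailto:|\\.\\.?/?$)", href)) return(NULL)
    if (grepl("^(\\.\\./)", href)) return(NULL)
    if (grepl("://", href, fixed = TRUE)) {
      ## absolute link: keep only true children of the listing
      if (!startsWith(href, sub("/*$", "/", baseURL))) return(NULL)
    }
    is_dir <- endsWith(href, "/")
    name <- curl::curl_unescape(sub("/$", "", basename(href)))
    if (!nzchar(name)) return(NULL)
    ## context text: table row if any, else trailing text sibling (pre)
    row <- xml2::xml_find_first(a, "ancestor::tr")
    ctx <- if (inherits(row, "xml_node"))
      paste(xml2::xml_text(xml2::xml_find_all(row, ".//td|.//th")),
            collapse = " ")
      else xml2::xml_text(xml2::xml_find_first(a, "following-sibling::text()[1]"))
    if (is.na(ctx)) ctx <- ""
    .entry_frame(name = name, isDirectory = is_dir,
                 modified = .parse_listing_date(ctx),
                 size = if (is_dir) NA_real_ else .parse_listing_size(ctx),
                 url = xml2::url_absolute(href, sub("/*$", "/", baseURL)))
  })
  out <- do.call(rbind, c(list(.entry_frame()), rows))
  rownames(out) <- NULL
  out
}

#' Parse a recursive index file
#'
#' Reads the single-request crawl format produced by
#' `ls -Rl > index.txt` at the repository root: blocks headed by
#' `<directory>:`, each followed by long-listing lines.  A mode string
#' starting with `d` marks a directory.  Both `--full-time` dates
#' (`2012-04-01 10:22:00 +0000`) and the classic month-name forms
#' (`Apr  1 10:22`, `Apr  1 2012`) are understood.
#'
#' @param text Index file content.
#' @param root Root URL the paths are resolved against.
#' @return `data.frame` with columns `path` (parent directory, relative,
#'   `"."` for the root), plus the entry columns of [parseListing()].
#' @export
parseIndexFile <- function(text, root) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  root <- sub("/*$", "", root)
  cur <- NULL
  out <- list()
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) { cur <- NULL; next }
    if (is.null(cur)) {
      if (!grepl(":$", line))
        stop("malformed index block header at line ", k, ": ", line,
             call. = FALSE)
      cur <- sub(":$", "", line)
      cur <- sub("^\\./?", "", cur)
      next
    }
    if (grepl("^total\\s", line)) next
    e <- .parse_ls_line(line)
    if (is.null(e)) next
    rel <- if (nzchar(cur)) paste0(cur, "/", e$name) else e$name
    e$url <- paste0(root, "/", rel, if (e$isDirectory) "/" else "")
    e$path <- if (nzchar(cur)) cur else "."
    out[[length(out) + 1L]] <- e
  }
  res <- do.call(rbind, c(list(cbind(.entry_frame(),
                                     data.frame(path = character()))), out))
  rownames(res) <- NULL
  res
}

.parse_ls_line <- function(line) {
  ## <mode> <links> <owner> <group> <size> <date...> <name with spaces>
  m <- regmatches(line, regexec(paste0(
    "^([dl-][rwxsStT-]{9})\\s+\\S+\\s+\\S+\\s+\\S+\\s+([0-9]+)\\s+",
    "([0-9]{4}-[0-9]{2}-[0-9]{2} [0-9]{2}:[0-9]{2}(?::[0-9]{2})?(?:\\.[0-9]+)?(?: [+-][0-9]{4})?",
    "|[A-Za-z]{3}\\s+[0-9]{1,2}\\s+(?:[0-9]{2}:[0-9]{2}|[0-9]{4}))\\s+(.+)$"),
    line, perl = TRUE))[[1]]
  if (!length(m)) return(NULL)
  is_dir <- startsWith(m[2], "d")
  date_txt <- m[4]
  mod <- .parse_index_date(date_txt)
  .entry_frame(name = sub("/$", "", m[5]), isDirectory = is_dir,
               modified = mod,
               size = if (is_dir) NA_real_ else as.numeric(m[3]),
               url = NA_character_)
}

.parse_index_date <- function(txt) {
  txt <- sub("\\.[0-9]+", "", txt)
  for (fmt in c("%Y-%m-%d %H:%M:%S %z", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%d %H:%M")) {
    d <- as.POSIXct(strptime(txt, fmt, tz = "UTC"))
    if (!is.na(d)) { attr(d, "tzone") <- "UTC"; return(d) }
  }
  ## month-name forms: "Apr  1 10:22" (current year) or "Apr  1 2012"
  m <- regmatches(txt, regexec(
    "^([A-Za-z]{3})\\s+([0-9]{1,2})\\s+([0-9]{2}:[0-9]{2}|[0-9]{4})$", txt))[[1]]
  if (!length(m)) return(as.POSIXct(NA))
  mon <- match(m[2], month.abb)
  if (is.na(mon)) return(as.POSIXct(NA))
  iso <- if (grepl(":", m[4]))
    sprintf("%s-%02d-%02d %s:00", format(Sys.Date(), "%Y"), mon,
            as.integer(m[3]), m[4])
  else
    sprintf("%s-%02d-%02d 00:00:00", m[4], mon, as.integer(m[3]))
  d <- as.POSIXct(strptime(iso, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  if (!is.na(d)) attr(d, "tzone") <- "UTC"
  d
}

## ---- fetching --------------------------------------------------------

.default_transport <- function(timeout) {
  force(timeout)
  function(url) {
    h <- curl::new_handle(timeout = timeout, followlocation = TRUE)
    res <- curl::curl_fetch_memory(url, handle = h)
    list(status = res$status_code, content = rawToChar(res$content))
  }
}

.fetch_with_retry <- function(transport, url, maxRetries, delay, first) {
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (!first || attempt > 1L) Sys.sleep(delay)
    res <- tryCatch(transport(url), error = function(e) list(status = NA,
                                                             error = conditionMessage(e)))
    if (!is.na(res$status %||% NA) && res$status < 400) return(res)
    if (attempt >= maxRetries)
      return(list(status = res$status %||% NA,
                  error = res$error %||% paste("HTTP", res$status)))
  }
}

## ---- walking ---------------------------------------------------------

#' Walk a crawl source depth-first
#'
#' Streams every entry of the repository tree in depth-first order:
#' each directory's entries appear in listing order, a parent always
#' before its children.  Every directory is fetched at most once (a
#' visited-URL set guards against listing cycles).  A directory whose
#' fetch fails after `maxRetries` attempts produces an error row and
#' the crawl continues with its siblings; an unreachable root is fatal.
#'
#' @param source A [crawlSource()].
#' @return `data.frame` with columns `depth` (1 = child of the root),
#'   `name`, `isDirectory`, `modified`, `size`, `url`, `status`
#'   (`"ok"` or `"error"`) and `message`.
#' @export
walkSource <- function(source) {
  validObject(source)
  switch(source@mode,
         http = .walk_http(source),
         local = .walk_local(source),
         index_file = .walk_index(source))
}

.walk_result <- function(rows) {
  out <- do.call(rbind, c(list(
    cbind(data.frame(depth = integer()), .entry_frame(),
          data.frame(status = character(), message = character()))), rows))
  rownames(out) <- NULL
  out
}

.walk_http <- function(source) {
  transport <- source@transport %||% .default_transport(source@timeout)
  visited <- new.env(parent = emptyenv())
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$first <- TRUE
  ## `own_row`: index of this directory's entry row (emitted by its
  ## parent's listing), marked "error" if the fetch ultimately fails
  recurse <- function(url, depth, own_row = NA_integer_) {
    key <- normalizeURL(url)
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    res <- .fetch_with_retry(transport, url, source@maxRetries,
                             source@politenessDelay, st$first)
    st$first <- FALSE
    if (!is.null(res$error)) {
      if (depth == 0)
        stop("root unreachable: ", source@root, " (", res$error, ")",
             call. = FALSE)
      st$rows[[own_row]]$status <- "error"
      st$rows[[own_row]]$message <- res$error
      return(invisible())
    }
    entries <- parseListing(res$content, url, source@dialect)
    for (i in seq_len(nrow(entries))) {
      st$rows[[length(st$rows) + 1L]] <- cbind(
        data.frame(depth = depth + 1L), entries[i, , drop = FALSE],
        data.frame(status = "ok", message = ""))
      if (entries$isDirectory[i])
        recurse(entries$url[i], depth + 1L, length(st$rows))
    }
  }
  recurse(sub("/*$", "/", source@root), 0L)
  .walk_result(st$rows)
}

.walk_local <- function(source) {
  root <- normalizePath(source@root)
  rows <- list()
  recurse <- function(dir, depth) {
    children <- sort(list.files(dir, all.files = FALSE), method = "radix")
    for (ch in children) {
      p <- file.path(dir, ch)
      info <- file.info(p)
      is_dir <- isTRUE(info$isdir)
      mod <- .as_utc(info$mtime)
      mod <- as.POSIXct(round(as.numeric(mod)), tz = "UTC",
                        origin = "1970-01-01")
      rows[[length(rows) + 1L]] <<- cbind(
        data.frame(depth = depth + 1L),
        .entry_frame(name = ch, isDirectory = is_dir, modified = mod,
                     size = if (is_dir) NA_real_ else info$size,
                     url = paste0("file://", p, if (is_dir) "/" else "")),
        data.frame(status = "ok", message = ""))
      if (is_dir) recurse(p, depth + 1L)
    }
  }
  recurse(root, 0L)
  .walk_result(rows)
}

.walk_index <- function(source) {
  text <- readChar(source@root, file.size(source@root), useBytes = TRUE)
  Encoding(text) <- "UTF-8"
  root_url <- paste0("file://", dirname(normalizePath(source@root)))
  entries <- parseIndexFile(text, root_url)
  ## blocks of the index arrive in ls -R order; rebuild a DFS stream
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  walk <- function(parent, depth) {
    here <- entries[entries$path == parent, , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      st$rows[[length(st$rows) + 1L]] <- cbind(
        data.frame(depth = depth + 1L),
        here[i, c("name", "isDirectory", "modified", "size", "url"),
             drop = FALSE],
        data.frame(status = "ok", message = ""))
      if (here$isDirectory[i]) {
        child <- if (parent == ".") here$name[i]
          else paste0(parent, "/", here$name[i])
        walk(child, depth + 1L)
      }
    }
  }
  walk(".", 0L)
  .walk_result(st$rows)
}
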