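## ---- SyntheticRepository ---------------------------------------------

## Label vocabularies.  Real repository codes (disease studies like gbm,
## ov, kich, ucec; center types; assay platforms) keep fixtures legible.
.vocab <- list(
  DiseaseStudy = c("gbm", "ov", "ucec", "kich", "brca", "luad", "lusc",
                   "coad", "kirc", "laml", "skcm", "stad", "thca", "prad"),
  CenterType = c("cgcc", "gsc", "bcr"),
  CenterDomain = c("mdanderson.org", "broad.mit.edu", "unc.edu",
                   "jhu-usc.edu", "hms.harvard.edu", "genome.wustl.edu",
                   "bcgsc.ca", "hudsonalpha.org"),
  Platform = c("mda_rppa_core", "illuminahiseq_rnaseqv2",
               "genome_wide_snp_6", "humanmethylation450",
               "agilentg4502a_07_3", "illuminaga_dnaseq", "mirnaseq",
               "abi_sanger", "affymetrix_u133a", "illuminaga_rnaseq",
               "humanmethylation27", "illuminahiseq_dnaseqc"),
  DataType = c("rppa", "rnaseq", "snp", "methylation", "mutations",
               "cna", "expression", "mirna")
)

setClass("SyntheticRepository",
  representation(
    nodes = "data.frame",        # path, isDirectory, modified, size
    initialNodes = "data.frame",
    clock = "POSIXct",
    createdAt = "POSIXct",
    eventLog = "data.frame",     # time, event, path, isDirectory, size
    seed = "integer",
    spec = "list"
  )
)

setValidity("SyntheticRepository", function(object) {
  nd <- object@nodes
  msgs <- character()
  if (!all(c("path", "isDirectory", "modified", "size") %in% names(nd)))
    msgs <- c(msgs, "nodes must have path, isDirectory, modified, size")
  else {
    if (anyDuplicated(nd$path)) msgs <- c(msgs, "duplicate node paths")
    depth <- lengths(strsplit(nd$path, "/", fixed = TRUE))
    if (any(!nd$isDirectory & depth < 7))
      msgs <- c(msgs, "files may only sit at depth >= 7 (below an archive)")
    parent <- .parent_path(nd$path)
    missing <- setdiff(setdiff(parent, ""), nd$path[nd$isDirectory])
    if (length(missing))
      msgs <- c(msgs, paste("orphan paths under missing directories:",
                            paste(head(missing, 3), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

.parent_path <- function(path) {
  out <- sub("/[^/]*$", "", path)
  out[!grepl("/", path)] <- ""
  out
}

.node_frame <- function(path = character(), isDirectory = logical(),
                        modified = as.POSIXct(character(), tz = "UTC"),
                        size = numeric()) {
  data.frame(path = path, isDirectory = isDirectory, modified = modified,
             size = size, stringsAsFactors = FALSE)
}

.event_frame <- function(time = as.POSIXct(character(), tz = "UTC"),
                         event = character(), path = character(),
                         isDirectory = logical(), size = numeric()) {
  data.frame(time = time, event = event, path = path,
             isDirectory = isDirectory, size = size, stringsAsFactors = FALSE)
}

#' Generate a synthetic seven-level repository
#'
#' Builds a deterministic, repository-shaped directory tree —
#' disease-study / center-type / center-domain / platform / data-type /
#' archive, with files inside the archives — whose labels are drawn
#' from realistic vocabularies (study codes like `gbm`, `ov`, `kich`,
#' `ucec`; platforms like `mda_rppa_core`).  The result is an
#' in-memory, evolvable mock of a live data repository: it can render
#' directory listings and recursive index files, be materialized to
#' disk or served over HTTP, and acts as ground-truth oracle for
#' crawls and temporal queries.
#'
#' @param breadths Integer vector of six per-level breadths
#'   `(diseases, centerTypes, centerDomains, platforms, dataTypes,
#'   archives)`, each >= 1.
#' @param filesPerArchive Number of files in each archive directory.
#' @param seed Integer seed; the same spec and seed always produce the
#'   identical repository.
#' @param start UTC timestamp used as the initial clock and modified
#'   date of every node.
#' @param platformSets Optional named list mapping a disease label to
#'   the exact platform labels it uses, overriding the platform breadth
#'   (this designs the disease-by-platform incidence directly).
#' @return A `SyntheticRepository` object.
#' @export
#' @examples
#' repo <- generateRepository(c(1, 1, 1, 1, 1, 1), filesPerArchive = 2,
#'                            seed = 7)
#' repoCounts(repo)   # 6 directories, 2 files
generateRepository <- function(breadths = c(4, 2, 2, 3, 2, 2),
                               filesPerArchive = 3, seed = 1,
                               start = as.POSIXct("2012-01-01 00:00:00",
                                                  tz = "UTC"),
                               platformSets = NULL) {
  breadths <- as.integer(breadths)
  if (length(breadths) != 6 || any(is.na(breadths)) || any(breadths < 1))
    stop("breadths must be six integers >= 1", call. = FALSE)
  if (filesPerArchive < 1) stop("filesPerArchive must be >= 1", call. = FALSE)
  start <- .as_utc(start)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  pick <- function(pool, n) {
    if (n <= length(pool)) sample(pool, n)
    else c(sample(pool), paste0(sample(pool, n - length(pool),
                                       replace = TRUE), "_",
                                sample(99, n - length(pool))))
  }
  paths <- character()
  dirs <- character()
  files <- .node_frame()
  diseases <- if (!is.null(platformSets)) names(platformSets)
    else pick(.vocab$DiseaseStudy, breadths[1])
  for (d in diseases) {
    dirs <- c(dirs, d)
    for (ct in pick(.vocab$CenterType, breadths[2])) {
      p_ct <- paste(d, ct, sep = "/")
      dirs <- c(dirs, p_ct)
      for (cd in pick(.vocab$CenterDomain, breadths[3])) {
        p_cd <- paste(p_ct, cd, sep = "/")
        dirs <- c(dirs, p_cd)
        plats <- if (!is.null(platformSets)) platformSets[[d]]
          else pick(.vocab$Platform, breadths[4])
        for (pl in plats) {
          p_pl <- paste(p_cd, pl, sep = "/")
          dirs <- c(dirs, p_pl)
          for (dt in pick(.vocab$DataType, breadths[5])) {
            p_dt <- paste(p_pl, dt, sep = "/")
            dirs <- c(dirs, p_dt)
            for (ai in seq_len(breadths[6])) {
              ar <- sprintf("%s_%s.%s.Level_3.%d.0.0", cd, d, pl, ai)
              p_ar <- paste(p_dt, ar, sep = "/")
              dirs <- c(dirs, p_ar)
              fn <- sprintf("%s.%s.data_%03d.txt", cd, pl,
                            sample(999, filesPerArchive))
              files <- rbind(files, .node_frame(
                path = paste(p_ar, fn, sep = "/"),
                isDirectory = FALSE,
                modified = rep(start, filesPerArchive),
                size = sample(200:4096, filesPerArchive, replace = TRUE)))
            }
          }
        }
      }
    }
  }
  nodes <- rbind(.node_frame(path = dirs, isDirectory = TRUE,
                             modified = rep(start, length(dirs)),
                             size = rep(NA_real_, length(dirs))),
                 files)
  nodes <- nodes[order(nodes$path, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  repo <- new("SyntheticRepository", nodes = nodes, initialNodes = nodes,
              clock = start, createdAt = start, eventLog = .event_frame(),
              seed = as.integer(seed),
              spec = list(breadths = breadths,
                          filesPerArchive = as.integer(filesPerArchive),
                          platformSets = platformSets))
  validObject(repo)
  repo
}

setMethod("show", "SyntheticRepository", function(object) {
  n <- repoCounts(object)
  cat("SyntheticRepository:", n["directories"], "directories,",
      n["files"], "files\n")
  cat("  clock:", formatDateTime(object@clock), " events:",
      nrow(object@eventLog), "\n")
  invisible(object)
})

#' Repository accessors and oracles
#'
#' `repoNodes` returns the current tree as a table; `repoCounts` the
#' directory/file totals; `repoClock` the logical clock; `repoEventLog`
#' the ordered add/remove/touch history; `repoEntries` the expected
#' depth-first crawl stream (the oracle against which crawler output is
#' checked).
#'
#' @param repo A `SyntheticRepository`.
#' @return See above.
#' @name repo-accessors
#' @export
repoNodes <- function(repo) repo@nodes

#' @rdname repo-accessors
#' @export
repoCounts <- function(repo) {
  c(directories = sum(repo@nodes$isDirectory),
    files = sum(!repo@nodes$isDirectory))
}

#' @rdname repo-accessors
#' @export
repoClock <- function(repo) repo@clock

#' @rdname repo-accessors
#' @export
repoEventLog <- function(repo) repo@eventLog

#' @rdname repo-accessors
#' @export
repoEntries <- function(repo) {
  nd <- repo@nodes
  out <- list()
  recurse <- function(parent, depth) {
    here <- nd[.parent_path(nd$path) == parent, , drop = FALSE]
    here <- here[order(basename(here$path), method = "radix"), , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      out[[length(out) + 1L]] <<- data.frame(
        depth = depth + 1L, name = basename(here$path[i]),
        path = here$path[i], isDirectory = here$isDirectory[i],
        modified = here$modified[i], size = here$size[i],
        stringsAsFactors = FALSE)
      if (here$isDirectory[i]) recurse(here$path[i], depth + 1L)
    }
  }
  recurse("", 0L)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- evolution -------------------------------------------------------

#' Evolve a synthetic repository
#'
#' Applies an ordered list of events to the repository under its
#' logical clock (evolution times are injected, never wall-clock, so
#' temporal scenarios replay deterministically).  Event forms:
#' `list(advance = seconds)` moves the clock; `list(add = path)` adds a
#' file (missing ancestor directories are created, each an `add` of its
#' own); `list(remove = path)` removes a file or a directory with its
#' whole subtree; `list(touch = path)` re-touches a file's content.
#'
#' Folder modified dates follow repository semantics: a folder's
#' modified date is the time its set of immediate children last changed
#' — so `add`/`remove` update the immediate parent only, and `touch`
#' updates nothing but the file itself.
#'
#' @param repo A `SyntheticRepository`.
#' @param events List of event specifications (see above).
#' @return The evolved repository; its event log replays to exactly the
#'   returned tree.
#' @export
evolveRepository <- function(repo, events) {
  nd <- repo@nodes
  log <- repo@eventLog
  clock <- repo@clock
  touch_parent <- function(path) {
    parent <- .parent_path(path)
    if (nzchar(parent)) nd$modified[nd$path == parent] <<- clock
  }
  for (ev in events) {
    stopifnot(is.list(ev), length(ev) >= 1)
    kind <- intersect(names(ev), c("advance", "add", "remove", "touch"))
    if (length(kind) != 1)
      stop("event must be one of advance/add/remove/touch", call. = FALSE)
    if (kind == "advance") {
      clock <- clock + as.numeric(ev$advance)
      next
    }
    path <- ev[[kind]]
    if (kind == "add") {
      if (path %in% nd$path) stop("path already exists: ", path, call. = FALSE)
      ## create missing ancestors, outermost first
      segs <- strsplit(path, "/", fixed = TRUE)[[1]]
      for (d in seq_along(segs)) {
        p <- paste(segs[seq_len(d)], collapse = "/")
        is_file <- d == length(segs)
        if (!is_file && p %in% nd$path) next
        size <- if (is_file) (ev$size %||% 1024) else NA_real_
        nd <- rbind(nd, .node_frame(path = p, isDirectory = !is_file,
                                    modified = clock, size = size))
        touch_parent(p)
        log <- rbind(log, .event_frame(time = clock, event = "add", path = p,
                                       isDirectory = !is_file, size = size))
      }
    } else if (kind == "remove") {
      if (!path %in% nd$path)
        stop("cannot remove nonexistent path: ", path, call. = FALSE)
      drop <- nd$path == path | startsWith(nd$path, paste0(path, "/"))
      nd <- nd[!drop, , drop = FALSE]
      touch_parent(path)
      log <- rbind(log, .event_frame(time = clock, event = "remove",
                                     path = path, isDirectory = NA,
                                     size = NA_real_))
    } else {  # touch
      i <- which(nd$path == path)
      if (!length(i))
        stop("cannot touch nonexistent path: ", path, call. = FALSE)
      if (nd$isDirectory[i])
        stop("touch applies to files, not directories: ", path, call. = FALSE)
      nd$modified[i] <- clock
      log <- rbind(log, .event_frame(time = clock, event = "touch",
                                     path = path, isDirectory = FALSE,
                                     size = nd$size[i]))
    }
  }
  nd <- nd[order(nd$path, method = "radix"), , drop = FALSE]
  rownames(nd) <- NULL
  rownames(log) <- NULL
  repo@nodes <- nd
  repo@eventLog <- log
  repo@clock <- clock
  validObject(repo)
  repo
}

#' Replay the event log
#'
#' Reconstructs the tree as it stood at time `t` by replaying the
#' event log over the initial tree — the independent oracle for the
#' engine's temporal queries.
#'
#' @param repo A `SyntheticRepository`.
#' @param t Timestamp; events with `time <= t` are applied.
#' @return Node table as of `t`.
#' @export
replayNodes <- function(repo, t = repo@clock) {
  t <- .as_utc(t)
  nd <- repo@initialNodes
  log <- repo@eventLog
  log <- log[log$time <= t, , drop = FALSE]
  for (i in seq_len(nrow(log))) {
    if (log$event[i] == "add") {
      nd <- rbind(nd, .node_frame(path = log$path[i],
                                  isDirectory = log$isDirectory[i],
                                  modified = log$time[i], size = log$size[i]))
      parent <- .parent_path(log$path[i])
      if (nzchar(parent)) nd$modified[nd$path == parent] <- log$time[i]
    } else if (log$event[i] == "remove") {
      drop <- nd$path == log$path[i] |
        startsWith(nd$path, paste0(log$path[i], "/"))
      nd <- nd[!drop, , drop = FALSE]
      parent <- .parent_path(log$path[i])
      if (nzchar(parent)) nd$modified[nd$path == parent] <- log$time[i]
    } else {
      nd$modified[nd$path == log$path[i]] <- log$time[i]
    }
  }
  nd <- nd[order(nd$path, method = "radix"), , drop = FALSE]
  rownames(nd) <- NULL
  nd
}

#' True file set at a point in time
#'
#' @param repo A `SyntheticRepository`.
#' @param t Timestamp at or after the repository's creation.
#' @return Character vector of file paths present at `t`.
#' @rdname replayNodes
#' @export
trueFileSet <- function(repo, t = repo@clock) {
  t <- .as_utc(t)
  if (t < repo@createdAt)
    stop("t predates the repository's creation", call. = FALSE)
  nd <- replayNodes(repo, t)
  sort(nd$path[!nd$isDirectory], method = "radix")
}

## ---- rendering -------------------------------------------------------

.fmt_dmy <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  sprintf("%02d-%s-%04d %02d:%02d", lt$mday, month.abb[lt$mon + 1],
          lt$year + 1900, lt$hour, lt$min)
}

#' Render one directory listing page
#'
#' Produces the autoindex HTML a web server would emit for a directory
#' of the repository, in the requested dialect: `"apache"` (the classic
#' `<pre>` variant), `"apache_table"`, `"nginx"`, or `"plain"` (bare
#' anchors, no metadata).  Listings include the parent link and
#' sort-control links that a crawler must ignore.
#'
#' @param repo A `SyntheticRepository`.
#' @param path Directory path relative to the root (`""` for the root).
#' @param dialect Listing dialect.
#' @return HTML string.
#' @export
renderListing <- function(repo, path = "",
                          dialect = c("apache", "apache_table", "nginx",
                                      "plain")) {
  dialect <- match.arg(dialect)
  path <- sub("/+$", "", path)
  if (path %in% c(".", "/")) path <- ""
  nd <- repo@nodes
  if (nzchar(path) && !path %in% nd$path[nd$isDirectory])
    stop("unknown path: ", path, call. = FALSE)
  here <- nd[.parent_path(nd$path) == path, , drop = FALSE]
  here <- here[order(basename(here$path), method = "radix"), , drop = FALSE]
  name <- basename(here$path)
  href <- paste0(curl::curl_escape(name), ifelse(here$isDirectory, "/", ""))
  shown <- paste0(name, ifelse(here$isDirectory, "/", ""))
  date <- .fmt_dmy(here$modified)
  size <- ifelse(here$isDirectory, "-", format(here$size, trim = TRUE,
                                               scientific = FALSE))
  title <- paste0("Index of /", path, if (nzchar(path)) "/")
  pad <- function(x, w) {
    formatC(x, width = -max(w, max(nchar(x)) + 2))
  }
  switch(dialect,
    apache = paste0(
      "<!DOCTYPE HTML PUBLIC \"-//W3C//DTD HTML 3.2 Final//EN\">\n",
      "<html>\n <head><title>", title, "</title></head>\n <body>\n",
      "<h1>", title, "</h1>\n<pre>",
      "<a href=\"?C=N;O=D\">Name</a>                    ",
      "<a href=\"?C=M;O=A\">Last modified</a>      ",
      "<a href=\"?C=S;O=A\">Size</a>\n<hr>",
      "<a href=\"../\">Parent Directory</a>\n",
      paste0("<a href=\"", href, "\">", shown, "</a>",
             vapply(shown, function(s)
               strrep(" ", max(1, 26 - nchar(s))), ""),
             date, "  ", format(size, width = 8), "\n", collapse = ""),
      "</pre><hr>\n</body></html>\n"),
    apache_table = paste0(
      "<html><head><title>", title, "</title></head><body>\n",
      "<h1>", title, "</h1>\n<table>\n",
      "<tr><th><a href=\"?C=N;O=D\">Name</a></th>",
      "<th><a href=\"?C=M;O=A\">Last modified</a></th>",
      "<th><a href=\"?C=S;O=A\">Size</a></th></tr>\n",
      "<tr><td><a href=\"../\">Parent Directory</a></td><td></td>",
      "<td>-</td></tr>\n",
      paste0("<tr><td><a href=\"", href, "\">", shown, "</a></td><td>",
             date, "</td><td>", size, "</td></tr>\n", collapse = ""),
      "</table>\n</body></html>\n"),
    nginx = paste0(
      "<html>\n<head><title>", title, "</title></head>\n",
      "<body bgcolor=\"white\">\n<h1>", title, "</h1><hr><pre>",
      "<a href=\"../\">../</a>\n",
      paste0("<a href=\"", href, "\">", shown, "</a>",
             vapply(shown, function(s)
               strrep(" ", max(1, 50 - nchar(s))), ""),
             date, " ", format(size, width = 19), "\n", collapse = ""),
      "</pre><hr></body>\n</html>\n"),
    plain = paste0(
      "<html><body>\n<ul>\n",
      paste0("<li><a href=\"", href, "\">", shown, "</a></li>\n",
             collapse = ""),
      "</ul>\n</body></html>\n")
  )
}

#' Render the whole repository as a recursive index file
#'
#' Emits the single-file `ls -Rl`-style index (blocks per directory,
#' long-listing lines with `--full-time` dates) that allows a road map
#' to be maintained from one HTTP request instead of one per directory.
#'
#' @param repo A `SyntheticRepository`.
#' @return Index text.
#' @export
renderIndex <- function(repo) {
  nd <- repo@nodes
  fmt_line <- function(row) {
    mode <- if (row$isDirectory) "drwxr-xr-x" else "-rw-r--r--"
    size <- if (row$isDirectory) 4096 else row$size
    sprintf("%s 1 tcga tcga %d %s %s", mode, as.integer(size),
            format(row$modified, "%Y-%m-%d %H:%M:%S +0000", tz = "UTC"),
            basename(row$path))
  }
  blocks <- character()
  dirs <- c("", sort(nd$path[nd$isDirectory], method = "radix"))
  for (d in dirs) {
    here <- nd[.parent_path(nd$path) == d, , drop = FALSE]
    here <- here[order(basename(here$path), method = "radix"), , drop = FALSE]
    lines <- vapply(seq_len(nrow(here)),
                    function(i) fmt_line(here[i, ]), "")
    header <- if (nzchar(d)) paste0("./", d, ":") else ".:"
    blocks <- c(blocks, paste0(header, "\n",
                               "total ", nrow(here), "\n",
                               paste0(lines, collapse = "\n")))
  }
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' Materialize the repository as a filesystem tree
#'
#' Writes directories and placeholder files (of the recorded sizes)
#' under `dir` and stamps the recorded modified dates on files and —
#' after all content exists — on directories, deepest first, so a
#' local-mode crawl of the materialized tree observes the same
#' metadata as an HTTP crawl of the served repository.
#'
#' @param repo A `SyntheticRepository`.
#' @param dir Target directory (created if needed; must be empty).
#' @return `dir`, invisibly.
#' @export
materializeRepository <- function(repo, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (length(list.files(dir))) stop("target directory not empty", call. = FALSE)
  nd <- repo@nodes
  for (p in nd$path[nd$isDirectory])
    dir.create(file.path(dir, p), recursive = TRUE, showWarnings = FALSE)
  fl <- nd[!nd$isDirectory, , drop = FALSE]
  for (i in seq_len(nrow(fl)))
    writeBin(as.raw(rep(120L, fl$size[i])), file.path(dir, fl$path[i]))
  for (i in seq_len(nrow(fl)))
    Sys.setFileTime(file.path(dir, fl$path[i]), fl$modified[i])
  dd <- nd[nd$isDirectory, , drop = FALSE]
  depth <- lengths(strsplit(dd$path, "/", fixed = TRUE))
  dd <- dd[order(-depth), , drop = FALSE]
  for (i in seq_len(nrow(dd)))
    Sys.setFileTime(file.path(dir, dd$path[i]), dd$modified[i])
  invisible(dir)
}

## ---- serving ---------------------------------------------------------

#' Serve the repository over local HTTP
#'
#' Starts a background R process serving the repository's directory
#' listings (and file payloads) on `127.0.0.1`, as a live crawl target.
#' The server counts every request it answers — the handle's
#' `requestCount()` reads the counter over a reserved, uncounted
#' `/__count` endpoint, which makes crawler efficiency (requests =
#' directories + 1) directly testable.  Call `$stop()` when done.
#'
#' @param repo A `SyntheticRepository`.
#' @param port TCP port (default: a random free port).
#' @param dialect Listing dialect to serve (see [renderListing()]).
#' @return Handle: list with `url`, `port`, `requestCount()`, `stop()`
#'   and the background `process`.
#' @export
serveRepository <- function(repo, port = NULL, dialect = "apache") {
  for (pkg in c("httpuv", "callr"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("serveRepository requires the ", pkg, " package", call. = FALSE)
  nd <- repo@nodes
  pages <- list("/" = renderListing(repo, "", dialect))
  for (p in nd$path[nd$isDirectory])
    pages[[paste0("/", p, "/")]] <- renderListing(repo, p, dialect)
  payloads <- list()
  fl <- nd[!nd$isDirectory, , drop = FALSE]
  for (i in seq_len(nrow(fl)))
    payloads[[paste0("/", fl$path[i])]] <- as.raw(rep(120L, fl$size[i]))
  if (is.null(port)) port <- httpuv::randomPort()
  proc <- callr::r_bg(function(pages, payloads, port) {
    counter <- new.env()
    counter$n <- 0L
    app <- list(call = function(req) {
      path <- req$PATH_INFO
      if (identical(path, "/__count"))
        return(list(status = 200L,
                    headers = list("Content-Type" = "text/plain"),
                    body = as.character(counter$n)))
      counter$n <- counter$n + 1L
      if (!is.null(pages[[path]]))
        return(list(status = 200L,
                    headers = list("Content-Type" = "text/html"),
                    body = pages[[path]]))
      if (!is.null(pages[[paste0(path, "/")]]))
        return(list(status = 301L,
                    headers = list("Location" = paste0(path, "/")),
                    body = ""))
      if (!is.null(payloads[[path]]))
        return(list(status = 200L,
                    headers = list("Content-Type" =
                                     "application/octet-stream"),
                    body = payloads[[path]]))
      list(status = 404L, headers = list("Content-Type" = "text/plain"),
           body = "not found")
    })
    httpuv::runServer("127.0.0.1", port, app)
  }, args = list(pages = pages, payloads = payloads, port = port))
  url <- sprintf("http://127.0.0.1:%d/", port)
  count_url <- paste0(url, "__count")
  fetch_count <- function() {
    res <- curl::curl_fetch_memory(count_url)
    as.integer(rawToChar(res$content))
  }
  ## wait for readiness
  deadline <- Sys.time() + 15
  repeat {
    ok <- tryCatch({ fetch_count(); TRUE }, error = function(e) FALSE)
    if (ok) break
    if (!proc$is_alive()) stop("fixture server failed to start", call. = FALSE)
    if (Sys.time() > deadline)
      stop("fixture server did not become ready", call. = FALSE)
    Sys.sleep(0.05)
  }
  list(url = url, port = port, process = proc,
       requestCount = fetch_count,
       stop = function() if (proc$is_alive()) proc$kill())
}

#' In-process transport over a synthetic repository
#'
#' A drop-in replacement for the crawler's HTTP transport that answers
#' listing requests directly from the repository object, counting each
#' request — HTTP semantics without sockets, for fast deterministic
#' crawl tests.
#'
#' @param repo A `SyntheticRepository`.
#' @param baseURL Root URL the transport pretends to serve.
#' @param dialect Listing dialect (see [renderListing()]).
#' @return List with `transport` (function for [crawlSource()]),
#'   `requestCount()` and `baseURL`.
#' @export
repoTransport <- function(repo, baseURL = "http://fixture.invalid/",
                          dialect = "apache") {
  baseURL <- sub("/*$", "/", baseURL)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  nd <- repo@nodes
  dir_paths <- nd$path[nd$isDirectory]
  transport <- function(url) {
    counter$n <- counter$n + 1L
    rel <- curl::curl_unescape(sub("/$", "", substring(url, nchar(baseURL) + 1)))
    if (!nzchar(rel))
      return(list(status = 200, content = renderListing(repo, "", dialect)))
    if (rel %in% dir_paths)
      return(list(status = 200, content = renderListing(repo, rel, dialect)))
    list(status = 404, content = "not found")
  }
  list(transport = transport, baseURL = baseURL,
       requestCount = function() counter$n)
}
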