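test_that("apache pre listings parse into ordered typed entries", {
  html <- paste0(
    "<html><body><h1>Index of /gbm/</h1><pre>",
    "<a href=\"?C=N;O=D\">Name</a> <a href=\"?C=M;O=A\">Last modified</a>\n",
    "<hr><a href=\"../\">Parent Directory</a>\n",
    "<a href=\"cgcc/\">cgcc/</a>            01-Apr-2012 10:22    -\n",
    "<a href=\"README.txt\">README.txt</a>   01-Apr-2012 10:23  1234\n",
    "</pre></body></html>")
  e <- parseListing(html, "http://x.org/gbm/", "apache")
  expect_identical(e$name, c("cgcc", "README.txt"))
  expect_identical(e$isDirectory, c(TRUE, FALSE))
  expect_identical(e$url, c("http://x.org/gbm/cgcc/", "http://x.org/gbm/README.txt"))
  expect_identical(e$modified,
                   as.POSIXct(c("2012-04-01 10:22:00", "2012-04-01 10:23:00"),
                              tz = "UTC"))
  expect_identical(e$size, c(NA, 1234))
})

test_that("apache table listings parse dates from the row cells", {
  html <- paste0(
    "<html><body><table>",
    "<tr><th><a href=\"?C=N;O=D\">Name</a></th><th>Last modified</th></tr>",
    "<tr><td><a href=\"../\">Parent Directory</a></td><td></td><td>-</td></tr>",
    "<tr><td><a href=\"ov/\">ov/</a></td><td>2012-04-01 10:22</td><td>-</td></tr>",
    "<tr><td><a href=\"a.txt\">a.txt</a></td><td>2012-04-02 08:00</td><td>77</td></tr>",
    "</table></body></html>")
  e <- parseListing(html, "http://x.org/", "apache")
  expect_identical(e$name, c("ov", "a.txt"))
  expect_identical(e$modified[1], as.POSIXct("2012-04-01 10:22:00", tz = "UTC"))
  expect_identical(e$size[2], 77)
})

test_that("pages with only parent and sort links yield no entries", {
  html <- paste0("<html><body><pre><a href=\"?C=N;O=D\">Name</a>",
                 "<a href=\"../\">Parent Directory</a></pre></body></html>")
  expect_identical(nrow(parseListing(html, "http://x.org/d/", "apache")), 0L)
})

test_that("every rendered dialect parses back to the tree's children", {
  repo <- tiny_repo()
  nd <- repoNodes(repo)
  root_children <- sort(basename(nd$path[!grepl("/", nd$path)]),
                        method = "radix")
  for (dialect in c("apache", "apache_table", "nginx", "plain")) {
    html <- renderListing(repo, "", dialect)
    parse_as <- if (dialect == "plain") "plain" else
      if (dialect == "nginx") "nginx" else "apache"
    e <- parseListing(html, "http://x.org/", parse_as)
    expect_identical(sort(e$name, method = "radix"), root_children,
                     info = dialect)
    if (dialect != "plain")
      expect_false(anyNA(e$modified), label = paste(dialect, "dates"))
  }
})

test_that("recursive index files parse blocks, modes and full dates", {
  text <- paste0(
    ".:\n",
    "total 1\n",
    "drwxr-xr-x 1 u g 4096 2012-04-01 10:22:00 +0000 gbm\n",
    "\n",
    "./gbm:\n",
    "total 1\n",
    "-rw-r--r-- 1 u g 512 2012-04-02 09:00:00 +0000 data.txt\n")
  e <- parseIndexFile(text, "http://x.org")
  expect_identical(nrow(e), 2L)
  expect_identical(e$isDirectory, c(TRUE, FALSE))
  expect_identical(e$path, c(".", "gbm"))
  expect_identical(e$url[2], "http://x.org/gbm/data.txt")
  expect_identical(e$modified[2], as.POSIXct("2012-04-02 09:00:00", tz = "UTC"))
  expect_error(parseIndexFile("not a header\nx", "http://x.org"),
               "malformed index block header")
})

test_that("classic ls month-name dates are understood", {
  e <- parseIndexFile(".:\ntotal 1\n-rw-r--r-- 1 u g 9 Apr  1 2012 f.txt\n",
                      "http://x.org")
  expect_identical(e$modified, as.POSIXct("2012-04-01", tz = "UTC"))
})

test_that("index round-trip recovers the whole fixture tree", {
  repo <- generateRepository(c(2, 1, 1, 2, 1, 1), filesPerArchive = 2,
                             seed = 5)
  e <- parseIndexFile(renderIndex(repo), "http://x.org")
  nd <- repoNodes(repo)
  got <- sort(ifelse(e$path == ".", e$name, paste(e$path, e$name, sep = "/")),
              method = "radix")
  expect_identical(got, sort(nd$path, method = "radix"))
  ## modified dates survive exactly (full-time format)
  key <- ifelse(e$path == ".", e$name, paste(e$path, e$name, sep = "/"))
  expect_identical(e$modified[order(key)],
                   nd$modified[order(nd$path)])
})

test_that("depth-first walk matches the oracle enumeration, parents first", {
  repo <- tiny_repo()
  w <- walkSource(repo_source(repo))
  oe <- repoEntries(repo)
  expect_identical(nrow(w), 8L)          # 6 directories + 2 files
  expect_identical(w$depth, oe$depth)
  expect_identical(w$name, oe$name)
  ## parent always precedes child in the stream
  seen <- character()
  for (i in seq_len(nrow(w))) {
    if (oe$depth[i] > 1) {
      parent <- dirname(oe$path[i])
      expect_true(parent %in% seen)
    }
    seen <- c(seen, oe$path[i])
  }
})

test_that("a failing directory drops its subtree but not its siblings", {
  repo <- generateRepository(c(2, 1, 1, 1, 1, 1), filesPerArchive = 1,
                             seed = 9)
  nd <- repoNodes(repo)
  top <- sort(nd$path[!grepl("/", nd$path)], method = "radix")
  bad <- top[1]
  tp <- repoTransport(repo)
  failing <- function(url) {
    if (grepl(paste0("/", bad, "/$"), url)) return(list(status = 500,
                                                        content = ""))
    tp$transport(url)
  }
  src <- crawlSource("http", tp$baseURL, politenessDelay = 0, maxRetries = 2,
                     transport = failing)
  w <- walkSource(src)
  expect_identical(w$status[w$name == bad], "error")
  expect_false(any(grepl(paste0("^http://fixture.invalid/", bad, "/."),
                         w$url[w$status == "ok"])))
  ## sibling study fully present
  expect_true(top[2] %in% w$name[w$status == "ok"])
  ## everything except the failing directory's subtree is streamed ok;
  ## the failing directory itself is the single error row
  expect_identical(sum(w$status == "ok"), nrow(repoEntries(repo)) -
                     sum(startsWith(repoNodes(repo)$path, paste0(bad, "/"))) -
                     1L)
  expect_identical(sum(w$status == "error"), 1L)
})

test_that("an unreachable root is fatal", {
  src <- crawlSource("http", "http://fixture.invalid/", politenessDelay = 0,
                     maxRetries = 1,
                     transport = function(url) list(status = 404, content = ""))
  expect_error(walkSource(src), "root unreachable")
})

test_that("URLs normalizing to the same key are fetched only once", {
  ## "a/" and "%61/" are the same directory under two spellings; the
  ## visited set keys on the normalized URL, so it is fetched once
  fetched <- new.env(); fetched$log <- character()
  transport <- function(url) {
    fetched$log <- c(fetched$log, url)
    if (grepl("fixture.invalid/$", url))
      return(list(status = 200, content = paste0(
        "<html><body><pre><a href=\"a/\">a/</a>\n",
        "<a href=\"%61/\">a/</a></pre></body></html>")))
    list(status = 200, content = "<html><body><pre></pre></body></html>")
  }
  src <- crawlSource("http", "http://fixture.invalid/", politenessDelay = 0,
                     transport = transport)
  w <- walkSource(src)
  expect_identical(length(fetched$log), 2L)   # root + the directory, once
  expect_identical(sum(w$isDirectory), 2L)    # both spellings still listed
})

test_that("http, local and index crawls of one repository agree", {
  repo <- generateRepository(c(1, 1, 1, 2, 1, 1), filesPerArchive = 2,
                             seed = 11)
  w_http <- walkSource(repo_source(repo))
  dir <- withr::local_tempdir()
  materializeRepository(repo, dir)
  w_local <- walkSource(crawlSource("local", dir))
  idx <- withr::local_tempfile(fileext = ".txt")
  writeLines(renderIndex(repo), idx)
  w_index <- walkSource(crawlSource("index_file", idx))
  key <- function(w) paste(w$depth, w$name)
  expect_identical(key(w_http), key(w_local))
  expect_identical(key(w_http), key(w_index))
  ## index preserves seconds; listings preserve minutes
  expect_identical(w_index$modified, repoEntries(repo)$modified)
  expect_identical(trunc(as.numeric(w_http$modified) / 60),
                   trunc(as.numeric(w_local$modified) / 60))
})

test_that("a live served fixture is crawled with one request per directory", {
  repo <- tiny_repo(seed = 13)
  h <- serveRepository(repo)
  on.exit(h$stop())
  w <- walkSource(crawlSource("http", h$url, politenessDelay = 0))
  expect_identical(paste(w$depth, w$name),
                   paste(repoEntries(repo)$depth, repoEntries(repo)$name))
  expect_identical(h$requestCount(),
                   unname(repoCounts(repo)["directories"] + 1L))
})

test_that("crawl sources validate their mode and root", {
  expect_error(crawlSource("local", tempfile()), "not resolvable")
  expect_error(crawlSource("ftp", "x"), "should be one of")
})
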