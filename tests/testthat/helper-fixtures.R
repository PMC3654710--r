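## Shared fixture builders.  All times are logical and UTC.

t0 <- function() as.POSIXct("2012-01-01 00:00:00", tz = "UTC")

days <- function(n) n * 86400

## smallest non-trivial repository: 1 path down to an archive, 2 files
tiny_repo <- function(seed = 7) {
  generateRepository(c(1, 1, 1, 1, 1, 1), filesPerArchive = 2, seed = seed)
}

## crawl a SyntheticRepository through the in-process HTTP transport
repo_source <- function(repo, dialect = "apache") {
  tp <- repoTransport(repo, dialect = dialect)
  crawlSource("http", tp$baseURL, politenessDelay = 0,
              transport = tp$transport)
}

scrape_repo <- function(graph, repo, scrape_time, dialect = "apache") {
  updateRoadmap(graph, repo_source(repo, dialect), scrape_time)
}

## file paths of a repository, sorted
repo_files <- function(repo) {
  nd <- repoNodes(repo)
  sort(nd$path[!nd$isDirectory], method = "radix")
}

## map fixture paths to the URLs minted through repoTransport's base
fixture_url <- function(path, isDirectory = FALSE) {
  if (!length(path)) return(character())
  paste0("http://fixture.invalid/",
         vapply(strsplit(path, "/", fixed = TRUE), function(segs)
           paste(curl::curl_escape(segs), collapse = "/"), ""),
         ifelse(isDirectory, "/", ""))
}

## random ResourceRecord generator for schema round-trip properties
random_record <- function(i, rng_kind = NULL) {
  kind <- rng_kind %||% sample(resourceKinds(), 1)
  depth_names <- c("gbm", "cgcc", "mdanderson.org", "mda_rppa_core",
                   "rppa", "archive_1.0.0")
  url <- paste0("http://repo.example.org/x", i, "/",
                paste(sample(letters, 5), collapse = ""),
                if (kind == "File") ".txt")
  links <- character()
  if (kind == "File") {
    k <- sample(0:6, 1)
    if (k > 0) {
      links <- vapply(seq_len(k), function(d)
        mintUUID(paste0("http://repo.example.org/anc", i, "/", d)), "")
      names(links) <- resourceKinds()[seq_len(k)]
    }
  }
  fs <- t0() + sample(0:10^6, 1)
  resourceRecord(url = url, kind = kind, firstSeen = fs,
                 lastSeen = fs + sample(0:10^5, 1),
                 lastModified = fs - sample(0:10^5, 1), links = links)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
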