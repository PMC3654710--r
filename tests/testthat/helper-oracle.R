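## Independent oracles: a naive backtracking triple-scan SPARQL
## evaluator, an rdflib (Python) bridge, and a random evolution
## scenario driver whose ground truth comes from event-log replay.

## ---- naive SPARQL evaluation (independent of the package's joins) ----

naive_sparql <- function(graph, query) {
  ast <- roadmapr:::sparqlParse(query, graph@prefixes)
  px <- graph@prefixes
  expand <- function(x) {
    for (p in names(px)) {
      pre <- paste0(p, ":")
      if (startsWith(x, pre)) return(paste0(px[[p]], substring(x, nchar(pre) + 1)))
    }
    x
  }
  contract <- function(x) {
    for (p in names(px)) {
      if (startsWith(x, px[[p]])) return(paste0(p, ":", substring(x, nchar(px[[p]]) + 1)))
    }
    x
  }
  tr <- graph@triples
  row_term <- function(i, slot) {
    v <- tr[[slot]][i]
    if (slot == "o" && tr$ot[i] != "iri") c("lit", v) else c("iri", expand(v))
  }
  tval <- function(term) {
    if (term$type == "iri") c("iri", term$value) else c("lit", term$value)
  }
  solutions <- list()
  recurse <- function(pi, binding) {
    if (pi > length(ast$patterns)) {
      solutions[[length(solutions) + 1L]] <<- binding
      return(invisible())
    }
    pat <- ast$patterns[[pi]]
    for (i in seq_len(nrow(tr))) {
      b <- binding
      ok <- TRUE
      for (slot in c("s", "p", "o")) {
        term <- pat[[slot]]
        val <- row_term(i, slot)
        if (term$type == "var") {
          if (!is.null(b[[term$value]])) {
            if (!identical(b[[term$value]], val)) { ok <- FALSE; break }
          } else b[[term$value]] <- val
        } else if (!identical(tval(term), val)) { ok <- FALSE; break }
      }
      if (ok) recurse(pi + 1L, b)
    }
  }
  recurse(1L, list())
  naive_filter <- function(f, b) {
    val <- function(e) {
      if (e$op == "term") {
        t <- e$term
        if (t$type == "var") return(b[[t$value]][2])
        if (t$type == "iri") return(t$value)
        return(t$value)
      }
      NULL
    }
    if (f$op == "term") stop("bare term filter not in corpus")
    if (f$op == "!") return(!naive_filter(f$l, b))
    if (f$op %in% c("&&", "||")) {
      l <- naive_filter(f$l, b); r <- naive_filter(f$r, b)
      return(if (f$op == "&&") l && r else l || r)
    }
    l <- val(f$l); r <- val(f$r)
    ln <- suppressWarnings(as.numeric(l)); rn <- suppressWarnings(as.numeric(r))
    if (!is.na(ln) && !is.na(rn)) { l <- ln; r <- rn }
    switch(f$op, "=" = l == r, "!=" = l != r, "<" = l < r, ">" = l > r,
           "<=" = l <= r, ">=" = l >= r)
  }
  if (length(ast$filters))
    solutions <- Filter(function(b)
      all(vapply(ast$filters, naive_filter, TRUE, b = b)), solutions)
  if (ast$form == "ASK") return(length(solutions) > 0)
  vars <- if (identical(ast$vars, "*"))
    unique(unlist(lapply(solutions, names))) else ast$vars
  rows <- vapply(solutions, function(b)
    paste(vapply(vars, function(v) {
      val <- b[[v]]
      if (is.null(val)) NA_character_
      else if (val[1] == "iri") contract(val[2]) else val[2]
    }, ""), collapse = "\r"), "")
  sort(unique(rows), method = "radix")
}

## canonical sorted row strings from a queryGraph() result, for set
## comparison against naive_sparql()
result_rows <- function(df) {
  if (!nrow(df)) return(character())
  sort(unique(do.call(paste, c(unname(as.list(df)), sep = "\r"))),
       method = "radix")
}

## ---- rdflib bridge ---------------------------------------------------

## parse a serialized graph with Python rdflib and run a SELECT query;
## returns sorted rows of "\r"-joined term strings (IRIs as full IRIs)
rdflib_select <- function(doc, format, query) {
  datafile <- tempfile(fileext = ".rdf")
  writeBin(charToRaw(doc), datafile)
  queryfile <- tempfile(fileext = ".rq")
  writeBin(charToRaw(query), queryfile)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph()",
    "g.parse(sys.argv[1], format=sys.argv[2])",
    "q = open(sys.argv[3]).read()",
    "rows = ['\\r'.join(str(v) for v in row) for row in g.query(q)]",
    "print('\\n'.join(sorted(rows)))"), script)
  out <- system2("python", c(script, datafile, format, queryfile),
                 stdout = TRUE)
  sort(out[nzchar(out)], method = "radix")
}

rdflib_triple_count <- function(doc, format) {
  datafile <- tempfile()
  writeBin(charToRaw(doc), datafile)
  out <- system2("python", c("-c", shQuote(paste0(
    "import rdflib; g = rdflib.Graph(); g.parse('", datafile,
    "', format='", format, "'); print(len(g))"))), stdout = TRUE)
  as.integer(out[1])
}

## ---- random evolution scenarios -------------------------------------

## Evolves a small repository through `n_scrapes` scrapes with random
## add/remove/touch events in between (event times minute-aligned, so
## listing dates lose nothing).  New paths are never reused, keeping
## presence intervals contiguous.  Returns the final repository, the
## built graph, and the scrape times.
run_scenario <- function(seed, n_scrapes = NULL) {
  set.seed(seed)
  n_scrapes <- n_scrapes %||% sample(3:6, 1)
  repo <- generateRepository(breadths = sample(1:2, 6, replace = TRUE),
                             filesPerArchive = sample(1:3, 1), seed = seed)
  graph <- roadmapGraph()
  times <- as.POSIXct(character(), tz = "UTC")
  counter <- 0L
  for (s in seq_len(n_scrapes)) {
    if (s > 1) {
      for (k in seq_len(sample(1:4, 1))) {
        repo <- evolveRepository(repo, list(list(advance = 60 * sample(1:10, 1))))
        nd <- repoNodes(repo)
        type <- sample(c("add", "remove", "touch"), 1,
                       prob = c(0.45, 0.35, 0.2))
        if (type == "add") {
          archives <- nd$path[nd$isDirectory &
                              lengths(strsplit(nd$path, "/")) == 6]
          if (!length(archives)) next
          counter <- counter + 1L
          repo <- evolveRepository(repo, list(list(
            add = paste0(sample(archives, 1), "/evofile_", seed, "_",
                         counter, ".txt"))))
        } else if (type == "remove") {
          victims <- if (runif(1) < 0.25)
            nd$path[nd$isDirectory & lengths(strsplit(nd$path, "/")) >= 5]
          else nd$path[!nd$isDirectory]
          if (!length(victims)) next
          repo <- evolveRepository(repo, list(list(remove = sample(victims, 1))))
        } else {
          files <- nd$path[!nd$isDirectory]
          if (!length(files)) next
          repo <- evolveRepository(repo, list(list(touch = sample(files, 1))))
        }
      }
    }
    repo <- evolveRepository(repo, list(list(advance = 60)))
    t_s <- repoClock(repo)
    res <- scrape_repo(graph, repo, t_s)
    graph <- res$graph
    times <- c(times, t_s)
  }
  attr(times, "tzone") <- "UTC"
  list(repo = repo, graph = graph, times = times)
}

## ground truth at a scrape time, as normalized URLs
oracle_urls_at <- function(repo, t, files_only = TRUE) {
  nd <- replayNodes(repo, t)
  if (files_only) nd <- nd[!nd$isDirectory, , drop = FALSE]
  sort(fixture_url(nd$path), method = "radix")
}

## strip trailing slashes so directory URLs compare cleanly
plain_urls <- function(urls) {
  sort(sub("/+$", "", urls), method = "radix")
}
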