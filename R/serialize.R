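## ---- term expansion / contraction -----------------------------------

.expand_iri <- function(x, prefixes) {
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", x))
  vapply(seq_along(x), function(i) {
    mi <- m[[i]]
    if (length(mi) && mi[2] %in% names(prefixes))
      paste0(prefixes[[mi[2]]], mi[3])
    else x[i]
  }, "")
}

.contract_iri <- function(x, prefixes) {
  out <- x
  for (pfx in names(prefixes)) {
    base <- prefixes[[pfx]]
    hit <- startsWith(out, base)
    out[hit] <- paste0(pfx, ":", substring(out[hit], nchar(base) + 1))
  }
  out
}

.literal_datatype <- function(ot) {
  c(string = NA_character_,
    anyURI = "http://www.w3.org/2001/XMLSchema#anyURI",
    dateTime = "http://www.w3.org/2001/XMLSchema#dateTime")[ot]
}

.ot_from_datatype <- function(dt) {
  if (is.na(dt) || !nzchar(dt)) return("string")
  switch(sub("^.*#", "", dt), anyURI = "anyURI", dateTime = "dateTime",
         "string")
}

.escape_nt <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescape_nt <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

.nt_lines <- function(graph) {
  tr <- graph@triples
  if (!nrow(tr)) return(character())
  px <- graph@prefixes
  s <- paste0("<", .expand_iri(tr$s, px), ">")
  p <- paste0("<", .expand_iri(tr$p, px), ">")
  o <- character(nrow(tr))
  iri <- tr$ot == "iri"
  o[iri] <- paste0("<", .expand_iri(tr$o[iri], px), ">")
  lit <- !iri
  dt <- .literal_datatype(tr$ot[lit])
  o[lit] <- paste0("\"", .escape_nt(tr$o[lit]), "\"",
                   ifelse(is.na(dt), "", paste0("^^<", dt, ">")))
  paste(s, p, o, ".")
}

## ---- writers ---------------------------------------------------------

#' Serialize a road-map graph
#'
#' Writes the graph as sorted N-Triples (byte-reproducible: the same
#' graph always serializes to the identical document), Turtle, or
#' RDF/XML.  [loadGraph()] reads any of the three back;
#' `load(serialize(g))` is graph-isomorphic to `g` (the graph contains
#' no blank nodes, so isomorphism is triple-set equality).
#'
#' @param graph A `RoadmapGraph`.
#' @param format One of `"ntriples"`, `"turtle"`, `"rdfxml"`.  For
#'   [loadGraph()] also `"auto"`, which sniffs the content.
#' @param file Path to write to, or `NULL` to return the document text.
#' @return The document as a single string (invisibly when `file` is
#'   given).
#' @export
serializeGraph <- function(graph, format = c("ntriples", "turtle", "rdfxml"),
                           file = NULL) {
  format <- match.arg(format)
  txt <- switch(format,
    ntriples = paste0(paste(sort(.nt_lines(graph), method = "radix"),
                            collapse = "\n"),
                      if (nrow(graph@triples)) "\n" else ""),
    turtle = .write_turtle(graph),
    rdfxml = .write_rdfxml(graph)
  )
  if (is.null(file)) return(txt)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(txt)
}

.write_turtle <- function(graph) {
  px <- graph@prefixes
  out <- c(paste0("@prefix ", names(px), ": <", px, "> ."), "")
  tr <- graph@triples
  if (nrow(tr)) {
    tr <- tr[order(tr$s, tr$p, tr$o, method = "radix"), , drop = FALSE]
    obj <- character(nrow(tr))
    iri <- tr$ot == "iri"
    obj[iri] <- tr$o[iri]
    dt <- tr$ot[!iri]
    obj[!iri] <- paste0("\"", .escape_nt(tr$o[!iri]), "\"",
                        ifelse(dt == "string", "",
                               paste0("^^xsd:", dt)))
    pred <- ifelse(tr$p == "rdf:type", "a", tr$p)
    for (subj in unique(tr$s)) {
      i <- which(tr$s == subj)
      body <- paste0("    ", pred[i], " ", obj[i],
                     c(rep(" ;", length(i) - 1), " ."))
      out <- c(out, subj, body, "")
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

.write_rdfxml <- function(graph) {
  px <- graph@prefixes
  ns_attrs <- setNames(as.list(unname(px)), paste0("xmlns:", names(px)))
  doc <- do.call(xml2::xml_new_root, c(list(.value = "rdf:RDF"), ns_attrs))
  tr <- graph@triples
  if (nrow(tr)) {
    tr <- tr[order(tr$s, tr$p, tr$o, method = "radix"), , drop = FALSE]
    for (subj in unique(tr$s)) {
      d <- xml2::xml_add_child(doc, "rdf:Description",
                               "rdf:about" = .expand_iri(subj, px))
      rows <- tr[tr$s == subj, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        if (rows$ot[i] == "iri") {
          xml2::xml_add_child(d, rows$p[i],
                              "rdf:resource" = .expand_iri(rows$o[i], px))
        } else {
          dt <- .literal_datatype(rows$ot[i])
          if (is.na(dt)) xml2::xml_add_child(d, rows$p[i], rows$o[i])
          else xml2::xml_add_child(d, rows$p[i], rows$o[i],
                                   "rdf:datatype" = unname(dt))
        }
      }
    }
  }
  as.character(doc)
}

## ---- readers ---------------------------------------------------------

#' Load a road-map graph from a serialized document
#'
#' @param x Document text, or a path to a file.
#' @param format Serialization format; `"auto"` (default) sniffs it.
#' @param base Base IRI bound to the `tcga:` prefix when the document
#'   does not declare prefixes (N-Triples).
#' @return A `RoadmapGraph` with its indexes rebuilt from the triples.
#' @rdname serializeGraph
#' @export
loadGraph <- function(x, format = c("auto", "ntriples", "turtle", "rdfxml"),
                      base = .default_base_iri) {
  format <- match.arg(format)
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    x <- readChar(x, file.size(x), useBytes = TRUE)
  if (format == "auto") {
    format <- if (grepl("^\\s*<\\?xml|<rdf:RDF", x)) "rdfxml"
      else if (grepl("@prefix", x, fixed = TRUE)) "turtle"
      else "ntriples"
  }
  parsed <- switch(format,
    ntriples = .parse_ntriples(x, roadmapPrefixes(base)),
    turtle = .parse_turtle(x, base),
    rdfxml = .parse_rdfxml(x, base)
  )
  g <- roadmapGraph()
  g@prefixes <- parsed$prefixes
  g@triples <- parsed$triples
  idx <- rebuildIndexes(g@triples)
  g@urlIndex <- idx$urlIndex
  g@kindIndex <- idx$kindIndex
  validObject(g)
  g
}

.parse_ntriples <- function(txt, prefixes) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pat <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
                "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>)?)",
                "\\s*\\.$")
  m <- regmatches(lines, regexec(pat, lines, perl = TRUE))
  bad <- which(vapply(m, length, 0L) == 0)
  if (length(bad))
    stop("malformed N-Triples at line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  tr <- lapply(m, function(mi) {
    o_raw <- mi[4]
    if (startsWith(o_raw, "<")) {
      o <- .contract_iri(substr(o_raw, 2, nchar(o_raw) - 1), prefixes)
      ot <- "iri"
    } else {
      dt <- NA_character_
      if (grepl("\\^\\^<", o_raw)) {
        dt <- sub("^.*\\^\\^<([^>]*)>$", "\\1", o_raw)
        o_raw <- sub("\\^\\^<[^>]*>$", "", o_raw)
      }
      o <- .unescape_nt(substr(o_raw, 2, nchar(o_raw) - 1))
      ot <- .ot_from_datatype(dt)
    }
    .triple_frame(.contract_iri(mi[2], prefixes),
                  .contract_iri(mi[3], prefixes), o, ot)
  })
  list(triples = do.call(rbind, c(list(.triple_frame()), tr)),
       prefixes = prefixes)
}

.tokenize_turtle <- function(txt) {
  pat <- paste0(
    "(@prefix)|",
    "(<[^<>\"{}|^`\\\\ ]*>)|",                       # IRIREF
    "(\"(?:[^\"\\\\]|\\\\.)*\")|",                   # STRING
    "(\\^\\^)|",
    "([A-Za-z][A-Za-z0-9_-]*)?:([A-Za-z0-9][A-Za-z0-9_.-]*)?|", # PNAME
    "\\b(a)\\b|",
    "([;,.])"
  )
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  toks <- regmatches(txt, list(m))[[1]]
  ## drop tokens inside comments: strip comment lines beforehand instead
  toks[nzchar(toks)]
}

.parse_turtle <- function(txt, base) {
  txt <- paste(grep("^\\s*#", strsplit(txt, "\n")[[1]], value = TRUE,
                    invert = TRUE), collapse = "\n")
  toks <- .tokenize_turtle(txt)
  prefixes <- roadmapPrefixes(base)
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[i] else NA_character_
  nxt <- function() { t <- toks[i]; i <<- i + 1L; t }
  triples <- list()
  term <- function(tok) {
    if (startsWith(tok, "<"))
      list(v = .contract_iri(substr(tok, 2, nchar(tok) - 1), prefixes),
           ot = "iri")
    else if (startsWith(tok, "\"")) {
      lex <- .unescape_nt(substr(tok, 2, nchar(tok) - 1))
      ot <- "string"
      if (identical(peek(), "^^")) {
        nxt()
        dt <- nxt()
        dt_iri <- if (startsWith(dt, "<")) substr(dt, 2, nchar(dt) - 1)
          else .expand_iri(dt, prefixes)
        ot <- .ot_from_datatype(dt_iri)
      }
      list(v = lex, ot = ot)
    } else list(v = tok, ot = "iri")
  }
  while (i <= n) {
    tok <- nxt()
    if (tok == "@prefix") {
      pfx <- sub(":$", "", nxt())
      iri <- nxt()
      prefixes[pfx] <- substr(iri, 2, nchar(iri) - 1)
      if (identical(peek(), ".")) nxt()
      next
    }
    subj <- term(tok)$v
    repeat {
      ptok <- nxt()
      pred <- if (ptok == "a") "rdf:type" else term(ptok)$v
      repeat {
        o <- term(nxt())
        triples[[length(triples) + 1L]] <-
          .triple_frame(subj, pred, o$v, o$ot)
        if (identical(peek(), ",")) nxt() else break
      }
      sep <- nxt()
      if (identical(sep, ";")) {
        if (identical(peek(), ".")) { nxt(); break }   # trailing ;
        next
      }
      if (identical(sep, ".") || is.na(sep)) break
      stop("Turtle parse error near token ", i, " (", sep, ")",
           call. = FALSE)
    }
  }
  list(triples = do.call(rbind, c(list(.triple_frame()), triples)),
       prefixes = prefixes)
}

.parse_rdfxml <- function(txt, base) {
  doc <- xml2::read_xml(txt)
  ns <- xml2::xml_ns(doc)
  prefixes <- roadmapPrefixes(base)
  for (pfx in names(ns))
    if (!pfx %in% c("xml")) prefixes[pfx] <- ns[[pfx]]
  descs <- xml2::xml_find_all(doc, "./*")
  triples <- lapply(descs, function(d) {
    subj <- .contract_iri(xml2::xml_attr(d, "about"), prefixes)
    props <- xml2::xml_children(d)
    rows <- lapply(props, function(p) {
      pred <- .contract_iri(.xml_full_name(p, ns), prefixes)
      res <- xml2::xml_attr(p, "resource")
      if (!is.na(res))
        return(.triple_frame(subj, pred, .contract_iri(res, prefixes), "iri"))
      dt <- xml2::xml_attr(p, "datatype")
      .triple_frame(subj, pred, xml2::xml_text(p), .ot_from_datatype(dt))
    })
    do.call(rbind, rows)
  })
  list(triples = do.call(rbind, c(list(.triple_frame()), triples)),
       prefixes = prefixes)
}

.xml_full_name <- function(node, ns) {
  nm <- xml2::xml_name(node, ns)    # "prefix:local" under the doc's map
  parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% names(ns))
    paste0(ns[[parts[1]]], parts[2])
  else nm
}

#' Test two graphs for isomorphism
#'
#' The vocabulary contains no blank nodes, so graph isomorphism reduces
#' to equality of the triple sets.
#'
#' @param g1,g2 `RoadmapGraph` objects.
#' @return Logical.
#' @export
isomorphicGraphs <- function(g1, g2) {
  identical(sort(.nt_lines(g1), method = "radix"),
            sort(.nt_lines(g2), method = "radix"))
}
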