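## A compact SPARQL 1.1 SELECT/ASK evaluator over the in-memory triple
## table.  Supported: PREFIX declarations, SELECT [DISTINCT] ?vars|*,
## ASK, basic graph patterns, FILTER with comparison and boolean
## operators, ORDER BY, LIMIT, OFFSET.  This covers the whole closed
## vocabulary and every dashboard query; OPTIONAL, property paths,
## aggregation and SERVICE federation are out of scope.

.sparql_tokenize <- function(query) {
  pat <- paste0(
    "(<[^<>\"{}|^`\\\\ \\t\\n]*>)",                 # IRIREF
    "|(\\?[A-Za-z_][A-Za-z0-9_]*)",                  # VAR
    "|(\"(?:[^\"\\\\]|\\\\.)*\")",                   # STRING
    "|((?:[A-Za-z][A-Za-z0-9_-]*)?:(?:[A-Za-z0-9_][A-Za-z0-9_.-]*)?)", # PNAME
    "|(-?[0-9]+(?:\\.[0-9]+)?)",                     # NUMBER
    "|([A-Za-z][A-Za-z0-9_]*)",                      # NAME / keyword
    "|(<=|>=|!=|&&|\\|\\||\\^\\^)",                  # 2-char ops
    "|([{}().;,*=<>!])"                              # 1-char ops
  )
  m <- gregexpr(pat, query, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), pos = integer()))
  data.frame(tok = regmatches(query, list(m))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

.sparql_error <- function(msg, pos) {
  stop(structure(class = c("roadmapr_sparql_error", "error", "condition"),
                 list(message = paste0("SPARQL syntax error at position ",
                                       pos, ": ", msg),
                      call = NULL)))
}

## Parse into an AST: list(form, distinct, vars, patterns, filters,
## orderBy, limit, offset, prefixes).
sparqlParse <- function(query, prefixes = roadmapPrefixes()) {
  tk <- .sparql_tokenize(query)
  i <- 1L
  n <- nrow(tk)
  peek <- function() if (i <= n) tk$tok[i] else NA_character_
  pos <- function() if (i <= n) tk$pos[i] else nchar(query) + 1L
  advance <- function() { t <- tk$tok[i]; i <<- i + 1L; t }
  expect <- function(what) {
    t <- peek()
    if (is.na(t) || toupper(t) != toupper(what))
      .sparql_error(paste0("expected '", what, "', found '",
                           if (is.na(t)) "<end>" else t, "'"), pos())
    advance()
  }
  kw <- function(what) !is.na(peek()) && toupper(peek()) == toupper(what)

  while (kw("PREFIX")) {
    advance()
    pn <- advance()
    if (is.na(pn) || !grepl(":$", pn))
      .sparql_error("expected prefix name", pos())
    iri <- advance()
    if (is.na(iri) || !startsWith(iri, "<"))
      .sparql_error("expected IRI after prefix name", pos())
    prefixes[sub(":$", "", pn)] <- substr(iri, 2, nchar(iri) - 1)
  }

  term <- function() {
    t <- peek()
    if (is.na(t)) .sparql_error("expected term", pos())
    p <- pos()
    advance()
    if (startsWith(t, "?")) return(list(type = "var", value = substring(t, 2)))
    if (startsWith(t, "<"))
      return(list(type = "iri", value = substr(t, 2, nchar(t) - 1)))
    if (startsWith(t, "\"")) {
      lex <- .unescape_nt(substr(t, 2, nchar(t) - 1))
      ot <- "string"
      if (identical(peek(), "^^")) {
        advance()
        dt <- advance()
        dt_iri <- if (startsWith(dt, "<")) substr(dt, 2, nchar(dt) - 1)
          else .expand_iri(dt, prefixes)
        ot <- .ot_from_datatype(dt_iri)
      }
      return(list(type = "literal", value = lex, ot = ot))
    }
    if (t == "a") return(list(type = "iri",
                              value = .expand_iri("rdf:type", prefixes)))
    if (grepl("^(?:[A-Za-z][A-Za-z0-9_-]*)?:", t))
      return(list(type = "iri", value = .expand_iri(t, prefixes)))
    if (grepl("^-?[0-9]", t))
      return(list(type = "literal", value = t, ot = "number"))
    .sparql_error(paste0("unexpected token '", t, "'"), p)
  }

  ## expression grammar for FILTER
  parse_or <- function() {
    e <- parse_and()
    while (identical(peek(), "||")) { advance(); e <- list(op = "||", l = e, r = parse_and()) }
    e
  }
  parse_and <- function() {
    e <- parse_rel()
    while (identical(peek(), "&&")) { advance(); e <- list(op = "&&", l = e, r = parse_rel()) }
    e
  }
  parse_rel <- function() {
    e <- parse_unary()
    if (!is.na(peek()) && peek() %in% c("=", "!=", "<", ">", "<=", ">=")) {
      op <- advance()
      e <- list(op = op, l = e, r = parse_unary())
    }
    e
  }
  parse_unary <- function() {
    if (identical(peek(), "!")) { advance(); return(list(op = "!", l = parse_unary())) }
    if (identical(peek(), "(")) {
      advance()
      e <- parse_or()
      expect(")")
      return(e)
    }
    list(op = "term", term = term())
  }

  form <- toupper(peek() %||% "")
  if (!form %in% c("SELECT", "ASK"))
    .sparql_error("query must be SELECT or ASK", pos())
  advance()
  distinct <- FALSE
  vars <- NULL
  if (form == "SELECT") {
    if (kw("DISTINCT")) { advance(); distinct <- TRUE }
    if (identical(peek(), "*")) { advance(); vars <- "*" }
    else {
      vars <- character()
      while (!is.na(peek()) && startsWith(peek(), "?"))
        vars <- c(vars, substring(advance(), 2))
      if (!length(vars)) .sparql_error("SELECT needs variables or *", pos())
    }
    if (kw("WHERE")) advance()
  }
  expect("{")
  patterns <- list()
  filters <- list()
  while (!is.na(peek()) && peek() != "}") {
    if (kw("FILTER")) {
      advance()
      expect("(")
      filters[[length(filters) + 1L]] <- parse_or()
      expect(")")
    } else {
      s <- term(); p <- term(); o <- term()
      patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
    }
    if (identical(peek(), ".")) advance()
  }
  expect("}")
  orderBy <- list()
  limit <- NA_integer_
  offset <- 0L
  while (!is.na(peek())) {
    if (kw("ORDER")) {
      advance(); expect("BY")
      repeat {
        dir <- 1L
        if (kw("ASC")) { advance(); expect("("); v <- advance(); expect(")") }
        else if (kw("DESC")) { advance(); dir <- -1L; expect("("); v <- advance(); expect(")") }
        else if (!is.na(peek()) && startsWith(peek(), "?")) v <- advance()
        else break
        orderBy[[length(orderBy) + 1L]] <- list(var = substring(v, 2), dir = dir)
      }
    } else if (kw("LIMIT")) { advance(); limit <- as.integer(advance()) }
    else if (kw("OFFSET")) { advance(); offset <- as.integer(advance()) }
    else .sparql_error(paste0("unexpected token '", peek(), "'"), pos())
  }
  list(form = form, distinct = distinct, vars = vars, patterns = patterns,
       filters = filters, orderBy = orderBy, limit = limit, offset = offset,
       prefixes = prefixes)
}

## Encode graph terms so IRIs and literals never collide while joining.
.enc_iri <- function(x) paste0("<", x, ">")
.enc_lit <- function(lex) paste0("\"", lex)
.sparql_encode_triples <- function(graph) {
  tr <- graph@triples
  px <- graph@prefixes
  iri <- tr$ot == "iri"
  data.frame(
    s = .enc_iri(.expand_iri(tr$s, px)),
    p = .enc_iri(.expand_iri(tr$p, px)),
    o = ifelse(iri, .enc_iri(.expand_iri(tr$o, px)), .enc_lit(tr$o)),
    stringsAsFactors = FALSE)
}
.encode_term <- function(t) {
  if (t$type == "iri") .enc_iri(t$value) else .enc_lit(t$value)
}
.decode_value <- function(x, prefixes) {
  iri <- startsWith(x, "<")
  out <- x
  out[iri] <- .contract_iri(substr(x[iri], 2, nchar(x[iri]) - 1), prefixes)
  out[!iri] <- substring(x[!iri], 2)
  out
}

.match_pattern <- function(enc, pattern) {
  cand <- enc
  vars <- character()
  for (slot in c("s", "p", "o")) {
    t <- pattern[[slot]]
    if (t$type == "var") vars[slot] <- t$value
    else cand <- cand[cand[[slot]] == .encode_term(t), , drop = FALSE]
  }
  ## repeated variable inside one pattern forces equality
  if (anyDuplicated(vars)) {
    for (v in unique(vars[duplicated(vars)])) {
      cols <- names(vars)[vars == v]
      for (col in cols[-1]) cand <- cand[cand[[cols[1]]] == cand[[col]], , drop = FALSE]
    }
  }
  out <- cand[, names(vars), drop = FALSE]
  names(out) <- vars
  out[, !duplicated(names(out)), drop = FALSE]
}

.eval_filter <- function(expr, bindings) {
  nr <- nrow(bindings)
  ev <- function(e) {
    if (e$op == "term") {
      t <- e$term
      if (t$type == "var") {
        if (!t$value %in% names(bindings))
          return(rep(NA_character_, nr))
        return(bindings[[t$value]])
      }
      return(rep(.encode_term(t), nr))
    }
    if (e$op == "!") return(!ev(e$l))
    l <- ev(e$l)
    r <- ev(e$r)
    if (e$op %in% c("&&", "||"))
      return(if (e$op == "&&") as.logical(l) & as.logical(r)
             else as.logical(l) | as.logical(r))
    lv <- .filter_operand(l)
    rv <- .filter_operand(r)
    ln <- suppressWarnings(as.numeric(lv))
    rn <- suppressWarnings(as.numeric(rv))
    if (!anyNA(ln) && !anyNA(rn)) { lv <- ln; rv <- rn }
    switch(e$op,
           "=" = lv == rv, "!=" = lv != rv,
           "<" = lv < rv, ">" = lv > rv,
           "<=" = lv <= rv, ">=" = lv >= rv)
  }
  ev(expr)
}

## strip the encoding marker; ISO-8601 UTC date-times compare correctly
## as plain strings, so no special date handling is needed here
.filter_operand <- function(x) {
  if (is.logical(x)) return(x)
  iri <- startsWith(x, "<")
  x[!iri] <- substring(x[!iri], 2)
  x
}

#' Query a graph with SPARQL
#'
#' Evaluates a SPARQL `SELECT` or `ASK` query against the graph.  The
#' supported language subset comprises `PREFIX` declarations, basic
#' graph patterns, `FILTER` with comparison (`=`, `!=`, `<`, `>`, `<=`,
#' `>=`) and boolean (`&&`, `||`, `!`) operators, `DISTINCT`,
#' `ORDER BY`, `LIMIT` and `OFFSET` — sufficient for every query over
#' the closed road-map vocabulary, including the dashboard queries.
#' The graph's own prefixes (`tcga:`, `rdf:`, `rdfs:`, `xsd:`) are
#' pre-declared and need not be repeated in the query.
#'
#' @param graph A `RoadmapGraph`.
#' @param query SPARQL query string.
#' @return For `SELECT`, a `data.frame` with one column per variable
#'   (IRIs in prefixed form, literals as their lexical form); for
#'   `ASK`, a single logical.
#' @export
#' @examples
#' g <- roadmapGraph()
#' queryGraph(g, "ASK { ?s rdf:type tcga:File }")
queryGraph <- function(graph, query) {
  ast <- sparqlParse(query, graph@prefixes)
  enc <- .sparql_encode_triples(graph)
  bindings <- data.frame(row.names = 1)[, 0, drop = FALSE]  # one empty row
  for (pattern in ast$patterns) {
    part <- .match_pattern(enc, pattern)
    common <- intersect(names(bindings), names(part))
    bindings <- if (ncol(part) == 0) {
      ## all-constant pattern: pure existence check
      if (nrow(part)) bindings else bindings[0, , drop = FALSE]
    } else if (ncol(bindings) == 0) part
      else if (length(common)) merge(bindings, part, by = common)
      else merge(bindings, part, by = NULL)
    if (!nrow(bindings) && ast$form == "ASK") break
  }
  for (f in ast$filters) {
    keep <- .eval_filter(f, bindings)
    bindings <- bindings[!is.na(keep) & keep, , drop = FALSE]
  }
  if (ast$form == "ASK") return(nrow(bindings) > 0)
  vars <- if (identical(ast$vars, "*")) names(bindings) else ast$vars
  missing_vars <- setdiff(vars, names(bindings))
  for (v in missing_vars) bindings[[v]] <- NA_character_
  out <- bindings[, vars, drop = FALSE]
  if (ast$distinct) out <- unique(out)
  if (length(ast$orderBy)) {
    keys <- lapply(ast$orderBy, function(ob) {
      k <- xtfrm(out[[ob$var]])
      if (ob$dir < 0) -k else k
    })
    out <- out[do.call(order, keys), , drop = FALSE]
  }
  if (ast$offset > 0) out <- out[-seq_len(min(ast$offset, nrow(out))), , drop = FALSE]
  if (!is.na(ast$limit)) out <- head(out, ast$limit)
  for (v in vars) out[[v]] <- .decode_value(out[[v]], graph@prefixes)
  rownames(out) <- NULL
  out
}
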