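# SPARQL-subset engine. Supported constructs: PREFIX, SELECT [DISTINCT]
# (variables, * or COUNT aggregates), WHERE with basic graph patterns
# (including ';'/',' abbreviations and [] blank-node property lists),
# FILTER, OPTIONAL, UNION, GROUP BY, ORDER BY; FROM clauses are accepted
# and ignored (the engine always queries the one supplied graph). Anything
# beyond this subset raises an unsupported-feature error rather than
# silently mis-evaluating.

sparql_unsupported <- c(
  "CONSTRUCT", "ASK", "DESCRIBE", "INSERT", "DELETE", "BIND", "VALUES",
  "MINUS", "SERVICE", "GRAPH", "EXISTS", "REGEX", "HAVING", "LIMIT",
  "OFFSET", "REDUCED", "SAMPLE", "SUM", "AVG", "MIN", "MAX", "CONCAT",
  "STR", "LANG"
)

sparql_keywords <- c(
  "PREFIX", "SELECT", "DISTINCT", "WHERE", "FILTER", "OPTIONAL", "UNION",
  "GROUP", "ORDER", "BY", "ASC", "DESC", "COUNT", "AS", "FROM",
  sparql_unsupported
)

sparql_tokenize <- function(q) {
  pattern <- paste0(
    '"(?:[^"\\\\]|\\\\.)*"', "|",
    "<[^>\\s]*>", "|",
    "\\?[A-Za-z_][A-Za-z0-9_]*", "|",
    "\\^\\^", "|",
    "&&|\\|\\||!=|<=|>=", "|",
    "[A-Za-z_][A-Za-z0-9_-]*:[A-Za-z_][A-Za-z0-9_.-]*", "|",
    "[A-Za-z_][A-Za-z0-9_-]*:", "|",
    "[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?", "|",
    "[A-Za-z_][A-Za-z0-9_]*", "|",
    "[{}()\\[\\];,.=<>!*/+-]"
  )
  q2 <- strip_hash_comments(q)
  m <- gregexpr(pattern, q2, perl = TRUE)[[1]]
  if (m[[1]] == -1) {
    rlang::abort("SPARQL parse error at position 1: empty query",
                 class = "scb_parse_error")
  }
  vals <- regmatches(q2, list(m))[[1]]
  tibble::tibble(value = vals, pos = as.integer(m))
}

# parser state: environment with tokens, index, prefixes
sp_state <- function(toks) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks; e$i <- 1L; e$prefixes <- character()
  e
}
sp_peek <- function(st, k = 0L) {
  i <- st$i + k
  if (i > nrow(st$toks)) "" else st$toks$value[[i]]
}
sp_pos <- function(st) {
  if (st$i > nrow(st$toks)) {
    if (nrow(st$toks) > 0) st$toks$pos[[nrow(st$toks)]] else 1L
  } else st$toks$pos[[st$i]]
}
sp_next <- function(st) {
  v <- sp_peek(st); st$i <- st$i + 1L; v
}
sp_fail <- function(st, what) {
  rlang::abort(sprintf("SPARQL parse error at position %d: expected %s, found '%s'",
                       sp_pos(st), what, sp_peek(st)),
               class = "scb_parse_error")
}
sp_expect <- function(st, value) {
  if (!sp_is_kw(st, value) && sp_peek(st) != value) sp_fail(st, value)
  sp_next(st)
}
sp_is_kw <- function(st, kw) toupper(sp_peek(st)) == kw
sp_check_unsupported <- function(st) {
  if (toupper(sp_peek(st)) %in% sparql_unsupported) {
    rlang::abort(paste0("Unsupported SPARQL feature: ",
                        toupper(sp_peek(st))),
                 class = "scb_unsupported_feature")
  }
}

sp_resolve_term <- function(st, tok) {
  if (startsWith(tok, "<")) {
    return(list(kind = "uri", value = substr(tok, 2L, nchar(tok) - 1L)))
  }
  if (startsWith(tok, "?")) {
    return(list(kind = "var", value = substring(tok, 2L)))
  }
  if (tok == "a") return(list(kind = "uri", value = RDF_TYPE))
  if (grepl("^[+-]?[0-9]", tok)) {
    return(list(kind = "literal", value = tok, numeric = TRUE))
  }
  if (startsWith(tok, "\"")) {
    val <- ttl_unescape(substr(tok, 2L, nchar(tok) - 1L))
    if (sp_peek(st) == "^^") {
      sp_next(st); sp_next(st)  # consume datatype; matching is lexical
    }
    return(list(kind = "literal", value = val, numeric = FALSE))
  }
  m <- regmatches(tok, regexec("^([A-Za-z_][A-Za-z0-9_-]*):(.*)$", tok))[[1]]
  if (length(m) == 3) {
    pfx <- m[[2]]
    if (!pfx %in% names(st$prefixes)) {
      rlang::abort(sprintf("SPARQL parse error at position %d: undeclared prefix '%s'",
                           sp_pos(st), pfx), class = "scb_parse_error")
    }
    return(list(kind = "uri", value = paste0(st$prefixes[[pfx]], m[[3]])))
  }
  sp_fail(st, "an RDF term")
}

parse_sparql <- function(query) {
  st <- sp_state(sparql_tokenize(query))
  # prologue
  repeat {
    if (sp_is_kw(st, "PREFIX")) {
      sp_next(st)
      pfx <- sub(":$", "", sp_next(st))
      iri <- sp_next(st)
      if (!startsWith(iri, "<")) sp_fail(st, "an IRI")
      st$prefixes[[pfx]] <- substr(iri, 2L, nchar(iri) - 1L)
    } else break
  }
  sp_check_unsupported(st)
  if (!sp_is_kw(st, "SELECT")) sp_fail(st, "SELECT")
  sp_next(st)
  distinct <- FALSE
  if (sp_is_kw(st, "DISTINCT")) { distinct <- TRUE; sp_next(st) }
  proj <- list(); aggs <- list()
  repeat {
    tok <- sp_peek(st)
    if (startsWith(tok, "?")) {
      proj[[length(proj) + 1L]] <- substring(sp_next(st), 2L)
    } else if (tok == "*") {
      sp_next(st); proj <- "*"; break
    } else if (tok == "(") {
      sp_next(st)
      sp_check_unsupported(st)
      if (!sp_is_kw(st, "COUNT")) sp_fail(st, "COUNT")
      sp_next(st); sp_expect(st, "(")
      cdist <- FALSE
      if (sp_is_kw(st, "DISTINCT")) { cdist <- TRUE; sp_next(st) }
      v <- sp_next(st)
      if (!startsWith(v, "?")) sp_fail(st, "a variable")
      sp_expect(st, ")")
      if (!sp_is_kw(st, "AS")) sp_fail(st, "AS")
      sp_next(st)
      out <- sp_next(st)
      if (!startsWith(out, "?")) sp_fail(st, "a variable")
      sp_expect(st, ")")
      aggs[[length(aggs) + 1L]] <- list(var = substring(v, 2L),
                                        as = substring(out, 2L),
                                        distinct = cdist)
    } else break
  }
  while (sp_is_kw(st, "FROM")) {  # dataset clauses accepted, ignored
    sp_next(st)
    if (!startsWith(sp_peek(st), "<")) sp_fail(st, "an IRI")
    sp_next(st)
  }
  if (sp_is_kw(st, "WHERE")) sp_next(st)
  group <- parse_ggp(st)
  group_by <- character(); order_by <- list()
  repeat {
    sp_check_unsupported(st)
    if (sp_is_kw(st, "GROUP")) {
      sp_next(st)
      if (!sp_is_kw(st, "BY")) sp_fail(st, "BY")
      sp_next(st)
      while (startsWith(sp_peek(st), "?")) {
        group_by <- c(group_by, substring(sp_next(st), 2L))
      }
    } else if (sp_is_kw(st, "ORDER")) {
      sp_next(st)
      if (!sp_is_kw(st, "BY")) sp_fail(st, "BY")
      sp_next(st)
      repeat {
        if (sp_is_kw(st, "DESC") || sp_is_kw(st, "ASC")) {
          dirn <- toupper(sp_next(st))
          sp_expect(st, "(")
          v <- sp_next(st)
          sp_expect(st, ")")
          order_by[[length(order_by) + 1L]] <-
            list(var = substring(v, 2L), desc = dirn == "DESC")
        } else if (startsWith(sp_peek(st), "?")) {
          order_by[[length(order_by) + 1L]] <-
            list(var = substring(sp_next(st), 2L), desc = FALSE)
        } else break
      }
    } else break
  }
  if (st$i <= nrow(st$toks)) {
    sp_check_unsupported(st)
    sp_fail(st, "end of query")
  }
  list(distinct = distinct, proj = proj, aggs = aggs, group = group,
       group_by = group_by, order_by = order_by)
}

# group graph pattern -> list of elements (bgp / filter / optional / union)
parse_ggp <- function(st) {
  sp_expect(st, "{")
  elements <- list()
  st$bnode_counter <- st$bnode_counter %||% 0L
  repeat {
    tok <- sp_peek(st)
    if (tok == "}") { sp_next(st); break }
    if (tok == "") sp_fail(st, "'}'")
    sp_check_unsupported(st)
    if (sp_is_kw(st, "FILTER")) {
      sp_next(st)
      sp_expect(st, "(")
      expr <- parse_expr(st)
      sp_expect(st, ")")
      elements[[length(elements) + 1L]] <- list(type = "filter", expr = expr)
      if (sp_peek(st) == ".") sp_next(st)
    } else if (sp_is_kw(st, "OPTIONAL")) {
      sp_next(st)
      g <- parse_ggp(st)
      elements[[length(elements) + 1L]] <- list(type = "optional", group = g)
      if (sp_peek(st) == ".") sp_next(st)
    } else if (tok == "{") {
      groups <- list(parse_ggp(st))
      while (sp_is_kw(st, "UNION")) {
        sp_next(st)
        groups[[length(groups) + 1L]] <- parse_ggp(st)
      }
      elements[[length(elements) + 1L]] <-
        if (length(groups) == 1) list(type = "group", group = groups[[1]])
        else list(type = "union", groups = groups)
      if (sp_peek(st) == ".") sp_next(st)
    } else {
      pats <- parse_triples_same_subject(st)
      elements[[length(elements) + 1L]] <- list(type = "bgp", patterns = pats)
      if (sp_peek(st) == ".") sp_next(st)
    }
  }
  elements
}

fresh_bnode_var <- function(st) {
  st$bnode_counter <- (st$bnode_counter %||% 0L) + 1L
  list(kind = "var", value = paste0(".bn", st$bnode_counter))
}

parse_triples_same_subject <- function(st) {
  pats <- list()
  if (sp_peek(st) == "[") {
    subj <- fresh_bnode_var(st)
    sp_next(st)
    pats <- c(pats, parse_property_list(st, subj))
    sp_expect(st, "]")
  } else {
    subj <- sp_resolve_term(st, sp_next(st))
    if (subj$kind == "literal") sp_fail(st, "a subject term")
  }
  pats <- c(pats, parse_property_list(st, subj))
  pats
}

parse_property_list <- function(st, subj) {
  pats <- list()
  repeat {
    tok <- sp_peek(st)
    if (tok %in% c(".", ";", "]", "}", "")) {
      if (tok == ";") { sp_next(st); next }
      break
    }
    sp_check_unsupported(st)
    verb <- sp_resolve_term(st, sp_next(st))
    if (verb$kind == "literal") sp_fail(st, "a predicate")
    repeat {
      otok <- sp_peek(st)
      if (otok == "[") {
        sp_next(st)
        bn <- fresh_bnode_var(st)
        pats[[length(pats) + 1L]] <- list(s = subj, p = verb, o = bn)
        pats <- c(pats, parse_property_list(st, bn))
        sp_expect(st, "]")
      } else {
        obj <- sp_resolve_term(st, sp_next(st))
        pats[[length(pats) + 1L]] <- list(s = subj, p = verb, o = obj)
      }
      if (sp_peek(st) == ",") sp_next(st) else break
    }
    if (sp_peek(st) == ";") { sp_next(st); next }
    break
  }
  pats
}

# expressions: || > && > comparison > unary ! > primary
parse_expr <- function(st) {
  left <- parse_and(st)
  while (sp_peek(st) == "||") {
    sp_next(st)
    left <- list(op = "||", l = left, r = parse_and(st))
  }
  left
}
parse_and <- function(st) {
  left <- parse_rel(st)
  while (sp_peek(st) == "&&") {
    sp_next(st)
    left <- list(op = "&&", l = left, r = parse_rel(st))
  }
  left
}
parse_rel <- function(st) {
  left <- parse_unary(st)
  op <- sp_peek(st)
  if (op %in% c("=", "!=", "<", ">", "<=", ">=")) {
    sp_next(st)
    return(list(op = op, l = left, r = parse_unary(st)))
  }
  left
}
parse_unary <- function(st) {
  if (sp_peek(st) == "!") {
    sp_next(st)
    return(list(op = "!", l = parse_unary(st)))
  }
  if (sp_peek(st) == "(") {
    sp_next(st)
    e <- parse_expr(st)
    sp_expect(st, ")")
    return(e)
  }
  sp_check_unsupported(st)
  tok <- sp_next(st)
  term <- sp_resolve_term(st, tok)
  list(op = "term", term = term)
}
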