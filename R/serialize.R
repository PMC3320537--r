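#' Write a semantic graph to Turtle or RDF/XML
#'
#' @param graph A `semantic_graph`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param file Optional output path.
#' @param include_inferred Include materialized triples (default TRUE).
#'   With FALSE only asserted triples are exported.
#' @return Document text, invisibly when `file` is given.
#' @export
write_graph <- function(graph, format = c("turtle", "rdfxml"), file = NULL,
                        include_inferred = TRUE) {
  if (!is.character(format) || !all(format %in% c("turtle", "rdfxml"))) {
    rlang::abort(paste0("Unsupported serialization format: ",
                        paste(format, collapse = ", ")),
                 class = "scb_format_error")
  }
  format <- match.arg(format)
  if (!include_inferred) graph <- asserted_only(graph)
  txt <- switch(format,
    turtle = write_turtle_text(graph),
    rdfxml = write_rdfxml_text(graph)
  )
  if (!is.null(file)) {
    writeLines(txt, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Read a semantic graph from Turtle or RDF/XML
#'
#' @param file Path or (for turtle) a character scalar of document text.
#' @param format `"turtle"` or `"rdfxml"`; guessed from the file extension
#'   when omitted.
#' @param namespaces Namespace table for the resulting graph.
#' @return A `semantic_graph` (all triples marked asserted).
#' @export
read_graph <- function(file, format = NULL, namespaces = default_namespaces()) {
  if (is.null(format)) {
    format <- if (grepl("\\.(rdf|xml|owl)$", file)) "rdfxml" else "turtle"
  }
  if (!format %in% c("turtle", "rdfxml")) {
    rlang::abort(paste0("Unsupported serialization format: ", format),
                 class = "scb_format_error")
  }
  txt <- if (file.exists(file)) paste(readLines(file, warn = FALSE), collapse = "\n") else file
  tt <- switch(format,
    turtle = parse_turtle(txt),
    rdfxml = parse_rdfxml(txt)
  )
  semantic_graph(tt, namespaces)
}

## ---- Turtle -----------------------------------------------------------

ttl_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  gsub("\t", "\\\\t", x)
}

ttl_unescape <- function(x) {
  x <- gsub("\\\\t", "\t", x)
  x <- gsub("\\\\r", "\r", x)
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

ttl_term <- function(x, ns) {
  ifelse(startsWith(x, "_:"), x, {
    c <- compact_uri(x, ns)
    ifelse(c == x, paste0("<", x, ">"), c)
  })
}

write_turtle_text <- function(graph) {
  ns <- graph$namespaces
  tt <- graph$triples
  header <- paste0("@prefix ", names(ns), ": <", unname(ns), "> .")
  if (nrow(tt) == 0) return(paste(c(header, ""), collapse = "\n"))
  obj <- ifelse(
    tt$is_literal,
    paste0("\"", ttl_escape(tt$object), "\"",
           ifelse(is.na(tt$datatype), "",
                  paste0("^^", ttl_term(tt$datatype, ns)))),
    ttl_term(tt$object, ns)
  )
  pred <- ifelse(tt$predicate == RDF_TYPE, "a", ttl_term(tt$predicate, ns))
  df <- tibble::tibble(s = ttl_term(tt$subject, ns), p = pred, o = obj)
  df <- dplyr::arrange(df, .data$s, .data$p, .data$o)
  body <- df |>
    dplyr::group_by(.data$s) |>
    dplyr::summarise(
      block = paste0(.data$s[[1]], " ",
                     paste(paste(.data$p, .data$o), collapse = " ;\n    "),
                     " ."),
      .groups = "drop"
    )
  paste(c(header, "", body$block), collapse = "\n")
}

# Minimal Turtle tokenizer/parser covering the dialect the writer emits
# plus common hand-written forms: @prefix, prefixed names, <uri>, "literal"
# (with escapes), ^^datatype, 'a', ';', ',', '.', '_:bnode', comments,
# bare integers/decimals.
parse_turtle <- function(txt) {
  toks <- ttl_tokenize(txt)
  prefixes <- character()
  i <- 1L
  n <- length(toks)
  out <- list(); nout <- 0L
  emit <- function(s, p, o, lit, dt) {
    nout <<- nout + 1L
    out[[nout]] <<- list(s, p, o, lit, dt)
  }
  resolve <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    if (startsWith(tok, "_:")) return(tok)
    if (tok == "a") return(RDF_TYPE)
    m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_-]*)?:(.*)$", tok))[[1]]
    if (length(m) == 0) {
      rlang::abort(paste0("Turtle parse error at token: ", tok),
                   class = "scb_parse_error")
    }
    pfx <- m[[2]]
    if (!pfx %in% names(prefixes)) {
      rlang::abort(paste0("Undeclared prefix: ", pfx), class = "scb_parse_error")
    }
    paste0(prefixes[[pfx]], m[[3]])
  }
  while (i <= n) {
    tok <- toks[[i]]
    if (tok %in% c("@prefix", "PREFIX")) {
      pfx <- sub(":$", "", toks[[i + 1L]])
      uri <- toks[[i + 2L]]
      prefixes[[pfx]] <- substr(uri, 2L, nchar(uri) - 1L)
      i <- i + if (tok == "@prefix") 4L else 3L
      next
    }
    s <- resolve(tok)
    i <- i + 1L
    repeat {
      p <- resolve(toks[[i]])
      i <- i + 1L
      repeat {
        otok <- toks[[i]]
        i <- i + 1L
        if (startsWith(otok, "\"")) {
          lit <- ttl_unescape(substr(otok, 2L, nchar(otok) - 1L))
          dt <- NA_character_
          if (i <= n && toks[[i]] == "^^") {
            dt <- resolve(toks[[i + 1L]])
            i <- i + 2L
          }
          emit(s, p, lit, TRUE, dt)
        } else if (grepl("^[+-]?[0-9]", otok)) {
          dt <- if (grepl("[.eE]", otok)) xsd_ns("double") else xsd_ns("integer")
          emit(s, p, otok, TRUE, dt)
        } else {
          emit(s, p, resolve(otok), FALSE, NA_character_)
        }
        if (i > n || toks[[i]] != ",") break
        i <- i + 1L
      }
      if (i > n || toks[[i]] != ";") break
      i <- i + 1L
      if (i <= n && toks[[i]] == ".") break  # trailing semicolon
    }
    if (i > n || toks[[i]] != ".") {
      rlang::abort(paste0("Turtle parse error near token ", i,
                          " (expected '.')"), class = "scb_parse_error")
    }
    i <- i + 1L
  }
  if (nout == 0L) {
    return(tibble::tibble(subject = character(), predicate = character(),
                          object = character(), is_literal = logical(),
                          datatype = character(), origin = character()))
  }
  out <- out[seq_len(nout)]
  tibble::tibble(
    subject = vapply(out, `[[`, "", 1L),
    predicate = vapply(out, `[[`, "", 2L),
    object = vapply(out, `[[`, "", 3L),
    is_literal = vapply(out, `[[`, NA, 4L),
    datatype = vapply(out, `[[`, "", 5L) |> (\(x) ifelse(is.na(x), NA_character_, x))(),
    origin = "asserted"
  )
}

# remove '#' comments that are outside quoted literals and <IRI> refs
strip_hash_comments <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- vapply(lines, function(l) {
    chars <- strsplit(l, "")[[1]]
    inq <- FALSE; inuri <- FALSE
    for (j in seq_along(chars)) {
      ch <- chars[[j]]
      if (ch == '"' && !inuri && (j == 1 || chars[[j - 1]] != "\\")) inq <- !inq
      if (ch == "<" && !inq) inuri <- TRUE
      if (ch == ">" && !inq) inuri <- FALSE
      if (ch == "#" && !inq && !inuri) return(substr(l, 1, j - 1))
    }
    l
  }, character(1), USE.NAMES = FALSE)
  paste(lines, collapse = "\n")
}

ttl_tokenize <- function(txt) {
  pattern <- paste0(
    '"(?:[^"\\\\]|\\\\.)*"', "|",   # quoted literal
    "<[^>]*>", "|",                  # uri ref
    "@prefix|PREFIX", "|",
    "\\^\\^", "|",
    "_:[A-Za-z0-9_]+", "|",
    "[A-Za-z][A-Za-z0-9_-]*:[A-Za-z_][A-Za-z0-9_.-]*", "|",  # prefixed name
    "[A-Za-z][A-Za-z0-9_-]*:", "|",  # bare prefix decl head like 'c2b2r:'
    "[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?", "|",
    "\\ba\\b", "|",
    "[;,.]"
  )
  txt <- strip_hash_comments(txt)
  m <- gregexpr(pattern, txt, perl = TRUE)[[1]]
  if (m[[1]] == -1) return(character())
  regmatches(txt, list(m))[[1]] |> unlist()
}

## ---- RDF/XML ----------------------------------------------------------

split_uri <- function(uri, ns) {
  for (i in order(nchar(ns), decreasing = TRUE)) {
    if (startsWith(uri, ns[[i]])) {
      local <- substring(uri, nchar(ns[[i]]) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
        return(c(prefix = names(ns)[[i]], local = local))
      }
    }
  }
  m <- regmatches(uri, regexec("^(.*[#/])([A-Za-z_][A-Za-z0-9_.-]*)$", uri))[[1]]
  if (length(m) == 3) return(c(prefix = NA, local = m[[3]], base = m[[2]]))
  rlang::abort(paste0("Cannot split URI for RDF/XML: ", uri),
               class = "scb_format_error")
}

write_rdfxml_text <- function(graph) {
  ns <- graph$namespaces
  tt <- graph$triples
  # collect ad-hoc namespaces for predicates outside the declared table
  extra <- character()
  for (p in unique(tt$predicate)) {
    sp <- split_uri(p, ns)
    if (is.na(sp[["prefix"]])) {
      if (!sp[["base"]] %in% extra) extra <- c(extra, sp[["base"]])
    }
  }
  if (length(extra) > 0) names(extra) <- paste0("nsx", seq_along(extra))
  allns <- c(ns, extra)
  attrs <- stats::setNames(as.list(unname(allns)),
                           paste0("xmlns:", names(allns)))
  doc <- do.call(xml2::xml_new_root, c(list("rdf:RDF"), attrs))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  tt <- dplyr::arrange(tt, .data$subject, .data$predicate, .data$object)
  for (s in unique(tt$subject)) {
    d <- if (startsWith(s, "_:")) {
      xml2::xml_add_child(doc, "rdf:Description", "rdf:nodeID" = substring(s, 3L))
    } else {
      xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    }
    rows <- tt[tt$subject == s, ]
    for (k in seq_len(nrow(rows))) {
      sp <- split_uri(rows$predicate[[k]], allns)
      tag <- paste0(sp[["prefix"]], ":", sp[["local"]])
      if (rows$is_literal[[k]]) {
        node <- xml2::xml_add_child(d, tag)
        xml2::xml_text(node) <- rows$object[[k]]
        if (!is.na(rows$datatype[[k]])) {
          xml2::xml_set_attr(node, "rdf:datatype", rows$datatype[[k]])
        }
      } else if (startsWith(rows$object[[k]], "_:")) {
        xml2::xml_add_child(d, tag, "rdf:nodeID" = substring(rows$object[[k]], 3L))
      } else {
        xml2::xml_add_child(d, tag, "rdf:resource" = rows$object[[k]])
      }
    }
  }
  as.character(doc)
}

parse_rdfxml <- function(txt) {
  doc <- tryCatch(xml2::read_xml(txt),
                  error = function(e) {
                    rlang::abort(paste0("RDF/XML parse error: ", conditionMessage(e)),
                                 class = "scb_parse_error")
                  })
  nsmap <- xml2::xml_ns(doc)
  rdfuri <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  rows <- list()
  rdf_attr <- function(node, name) {
    v <- xml2::xml_attr(node, paste0("rdf:", name), ns = nsmap)
    if (is.na(v)) v <- xml2::xml_attr(node, name)
    v
  }
  for (d in xml2::xml_children(doc)) {
    about <- rdf_attr(d, "about")
    nodeid <- rdf_attr(d, "nodeID")
    s <- if (!is.na(about)) about else paste0("_:", nodeid)
    # typed node element form: <c2b2r:Drug rdf:about=...>
    dn <- xml2::xml_name(d, nsmap)
    if (dn != "rdf:Description") {
      puri <- xml_qname_to_uri(d, nsmap)
      rows[[length(rows) + 1L]] <-
        list(s, RDF_TYPE, puri, FALSE, NA_character_)
    }
    for (p in xml2::xml_children(d)) {
      puri <- xml_qname_to_uri(p, nsmap)
      res <- rdf_attr(p, "resource")
      nid <- rdf_attr(p, "nodeID")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- list(s, puri, res, FALSE, NA_character_)
      } else if (!is.na(nid)) {
        rows[[length(rows) + 1L]] <- list(s, puri, paste0("_:", nid), FALSE, NA_character_)
      } else {
        dt <- rdf_attr(p, "datatype")
        rows[[length(rows) + 1L]] <-
          list(s, puri, xml2::xml_text(p), TRUE,
               if (is.na(dt)) NA_character_ else dt)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(subject = character(), predicate = character(),
                          object = character(), is_literal = logical(),
                          datatype = character(), origin = character()))
  }
  tibble::tibble(
    subject = vapply(rows, `[[`, "", 1L),
    predicate = vapply(rows, `[[`, "", 2L),
    object = vapply(rows, `[[`, "", 3L),
    is_literal = vapply(rows, `[[`, NA, 4L),
    datatype = vapply(rows, function(r) r[[5L]] %||% NA_character_, NA_character_),
    origin = "asserted"
  )
}

xml_qname_to_uri <- function(node, nsmap) {
  qn <- xml2::xml_name(node, nsmap)
  parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[[1]] %in% names(nsmap)) {
    return(paste0(nsmap[[parts[[1]]]], parts[[2]]))
  }
  qn
}
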