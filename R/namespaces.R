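#' Default namespace table
#'
#' The ontology lives in the `c2b2r` namespace; BioPAX (`bp`) and the
#' Relation Ontology (`ro`) contribute the structure/evidence/xref and
#' participation properties, mirroring how the field's pathway exchange
#' formats name them. These prefixes are used when serializing and when
#' expanding prefixed names in SPARQL and configuration files.
#'
#' @param base Base URI for the ontology namespace (`c2b2r`).
#' @return Named character vector, prefix -> URI base.
#' @export
default_namespaces <- function(base = scb_base_uri()) {
  c(
    c2b2r = base,
    bp    = "http://www.biopax.org/release/biopax-level3.owl#",
    ro    = "http://www.obofoundry.org/ro/ro.owl#",
    rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
    owl   = "http://www.w3.org/2002/07/owl#",
    xsd   = "http://www.w3.org/2001/XMLSchema#"
  )
}

#' Default ontology base URI
#' @return A string.
#' @export
scb_base_uri <- function() "http://chem2bio2rdf.org/chem2bio2owl#"

# Expand a prefixed name ("c2b2r:Drug") to a full URI using a namespace table.
# Strings that are already absolute URIs pass through untouched.
expand_curie <- function(x, ns = default_namespaces()) {
  out <- x
  idx <- grepl("^[A-Za-z][A-Za-z0-9_]*:", x) & !grepl("^(https?|urn|file):", x)
  if (any(idx)) {
    pfx <- sub(":.*$", "", x[idx])
    loc <- sub("^[^:]*:", "", x[idx])
    bases <- unname(ns[pfx])
    bad <- is.na(bases)
    if (any(bad)) {
      rlang::abort(
        paste0("Unknown namespace prefix: ", paste(unique(pfx[bad]), collapse = ", ")),
        class = "scb_config_error"
      )
    }
    out[idx] <- paste0(bases, loc)
  }
  out
}

# Compact a full URI to a prefixed name where a namespace matches (longest wins).
compact_uri <- function(x, ns = default_namespaces()) {
  ord <- order(nchar(ns), decreasing = TRUE)
  ns <- ns[ord]
  out <- x
  done <- is.na(x)
  for (i in seq_along(ns)) {
    hit <- !done & startsWith(x, ns[[i]])
    hit[is.na(hit)] <- FALSE
    if (any(hit)) {
      local <- substring(x[hit], nchar(ns[[i]]) + 1L)
      ok <- grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)
      out[hit][ok] <- paste0(names(ns)[[i]], ":", local[ok])
      done[hit][ok] <- TRUE
    }
  }
  out
}

# Shorthand constructors for the vocabularies used throughout.
c2b2r <- function(local, base = scb_base_uri()) paste0(base, local)
bp_ns  <- function(local) paste0("http://www.biopax.org/release/biopax-level3.owl#", local)
ro_ns  <- function(local) paste0("http://www.obofoundry.org/ro/ro.owl#", local)
rdf_ns <- function(local) paste0("http://www.w3.org/1999/02/22-rdf-syntax-ns#", local)
rdfs_ns <- function(local) paste0("http://www.w3.org/2000/01/rdf-schema#", local)
owl_ns <- function(local) paste0("http://www.w3.org/2002/07/owl#", local)
xsd_ns <- function(local) paste0("http://www.w3.org/2001/XMLSchema#", local)

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_SUBCLASSOF <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"

# Percent-encode characters unsafe inside a URI fragment identifier.
uri_sanitize <- function(x) {
  vapply(x, function(s) {
    utf8 <- charToRaw(enc2utf8(as.character(s)))
    ok <- rawToChar(utf8, multiple = TRUE) %in%
      c(letters, LETTERS, as.character(0:9), "-", "_", ".", "~")
    chars <- ifelse(ok, rawToChar(utf8, multiple = TRUE),
                    paste0("%", toupper(as.character(utf8))))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
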