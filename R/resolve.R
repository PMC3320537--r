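#' Cross-reference record
#'
#' @param db Source database name (non-empty).
#' @param id Identifier in that source (non-empty).
#' @param comments Optional free-text comments.
#' @return A one-row tibble with columns `db`, `id`, `comments`.
#' @export
xref <- function(db, id, comments = NA_character_) {
  db <- as.character(db); id <- as.character(id)
  if (any(!nzchar(db)) || any(!nzchar(id)) || any(is.na(db)) || any(is.na(id))) {
    rlang::abort("Xref DB and ID must be non-empty", class = "scb_validation_error")
  }
  tibble::tibble(db = db, id = id, comments = as.character(comments))
}

# Prefix used when minting instance URIs, one per entity kind. Compounds use
# the bare word so CID 5591 becomes ...#compound5591.
kind_prefix <- function(kind) {
  prefixes <- c(
    compound = "compound", drug = "drug", protein = "protein",
    disease = "disease", side_effect = "sideeffect", pathway = "pathway",
    literature = "literature", bioassay = "bioassay", interaction = "interaction"
  )
  if (!kind %in% names(prefixes)) {
    rlang::abort(paste0("Unknown entity kind: ", kind), class = "scb_lookup_error")
  }
  prefixes[[kind]]
}

#' Mint a deterministic instance URI
#'
#' The URI is the namespace base, a kind-specific prefix, and the primary
#' identifier with URI-unsafe characters percent-encoded. Minting is
#' injective over (kind, id): distinct kinds or ids never collide.
#'
#' @param kind Entity kind (`"compound"`, `"drug"`, `"protein"`,
#'   `"disease"`, `"side_effect"`, `"pathway"`, `"literature"`,
#'   `"bioassay"`, `"interaction"`).
#' @param primary_id Primary identifier, non-empty.
#' @param base Namespace base URI.
#' @return URI string.
#' @examples
#' mint_uri("compound", 5591)
#' @export
mint_uri <- function(kind, primary_id, base = scb_base_uri()) {
  primary_id <- as.character(primary_id)
  if (!nzchar(primary_id)) {
    rlang::abort("primary_id must be non-empty", class = "scb_validation_error")
  }
  # surrogate CIDs (negative integers) serialize as compoundF<n>
  if (kind == "compound" && grepl("^-[0-9]+$", primary_id)) {
    return(paste0(base, "compoundF", substring(primary_id, 2L)))
  }
  paste0(base, kind_prefix(kind), uri_sanitize(primary_id))
}

#' Resolution context
#'
#' Holds the offline InChI-to-CID lookup, the disease-term table, the
#' namespace base and the registry of minted surrogate CIDs. Surrogates are
#' negative integers, a namespace disjoint from real (positive) PubChem
#' CIDs, handed out deterministically: within one context the same
#' unresolved key always receives the same surrogate.
#'
#' @param lookup Data frame with columns `inchi`, `cid` (positive integers),
#'   or NULL.
#' @param do_terms Disease-term table with columns `doid`, `label`,
#'   `synonyms` (pipe-separated), `parent_doid`, or NULL.
#' @param base Namespace base URI.
#' @param disease_threshold Token-set Jaccard threshold for fuzzy disease
#'   matching (default 0.8).
#' @return A `resolution_context` object.
#' @export
resolution_context <- function(lookup = NULL, do_terms = NULL,
                               base = scb_base_uri(),
                               disease_threshold = 0.8) {
  if (!is.null(lookup)) {
    lookup <- tibble::as_tibble(lookup)
    stopifnot(all(c("inchi", "cid") %in% names(lookup)))
    if (any(lookup$cid <= 0)) {
      rlang::abort("Lookup CIDs must be positive integers",
                   class = "scb_validation_error")
    }
  }
  if (!is.null(do_terms)) do_terms <- tibble::as_tibble(do_terms)
  structure(
    list(
      lookup = lookup, do_terms = do_terms, base = base,
      disease_threshold = disease_threshold,
      surrogates = new.env(parent = emptyenv())
    ),
    class = "resolution_context"
  )
}

surrogate_cid <- function(ctx, key) {
  if (!is.null(ctx$surrogates[[key]])) return(ctx$surrogates[[key]])
  n <- length(ls(ctx$surrogates)) + 1L
  ctx$surrogates[[key]] <- -n
  -n
}

#' Resolve a compound to its primary CID
#'
#' Resolution order: an explicit PubChem cross-reference wins; otherwise the
#' InChI is looked up in the offline table; otherwise a surrogate CID is
#' minted from the reserved (negative) namespace. All input
#' cross-references are retained on the resolved entity.
#'
#' @param xrefs Tibble of cross-references (`db`, `id`, optional
#'   `comments`), possibly empty.
#' @param inchi Optional InChI string.
#' @param ctx A `resolution_context`.
#' @return One-row tibble: `kind`, `primary_id`, `is_surrogate`, `uri`, and
#'   list-column `xrefs`.
#' @export
resolve_compound <- function(xrefs = NULL, inchi = NULL, ctx = resolution_context()) {
  if ((is.null(xrefs) || nrow(xrefs) == 0) && is.null(inchi)) {
    rlang::abort("resolve_compound needs xrefs or an InChI",
                 class = "scb_validation_error")
  }
  if (is.null(xrefs)) xrefs <- xref("placeholder", "x")[0, ]
  xrefs <- tibble::as_tibble(xrefs)
  if (!"comments" %in% names(xrefs)) xrefs$comments <- NA_character_
  pc <- unique(xrefs$id[tolower(xrefs$db) == "pubchem"])
  if (length(pc) > 1) {
    rlang::abort(
      paste0("Conflicting PubChem xrefs: ", paste(pc, collapse = ", ")),
      class = "scb_ambiguity_error"
    )
  }
  is_surrogate <- FALSE
  if (length(pc) == 1) {
    cid <- as.integer(pc)
  } else if (!is.null(inchi) && !is.null(ctx$lookup) &&
             inchi %in% ctx$lookup$inchi) {
    cid <- ctx$lookup$cid[match(inchi, ctx$lookup$inchi)]
  } else {
    key <- if (!is.null(inchi)) paste0("inchi:", inchi) else {
      paste0("xref:", paste(sort(paste(xrefs$db, xrefs$id)), collapse = "|"))
    }
    cid <- surrogate_cid(ctx, key)
    is_surrogate <- TRUE
  }
  tibble::tibble(
    kind = "compound",
    primary_id = as.character(cid),
    is_surrogate = is_surrogate,
    uri = mint_uri("compound", cid, ctx$base),
    xrefs = list(xrefs)
  )
}

normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("\\s+", " ", trimws(x))
}

token_jaccard <- function(a, b) {
  ta <- unique(strsplit(a, " ", fixed = TRUE)[[1]])
  tb <- unique(strsplit(b, " ", fixed = TRUE)[[1]])
  if (length(ta) == 0 && length(tb) == 0) return(1)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Map a free-text disease term to a Disease Ontology identifier
#'
#' Match order: exact DOID; case/punctuation-normalized exact match on a
#' label or synonym; token-set Jaccard similarity at or above the context
#' threshold, ties broken by the lexicographically smallest DOID. Terms
#' with no candidate above the threshold yield NULL (the record is excluded
#' downstream), with a logged message rather than an error.
#'
#' @param term Free text or a DOID.
#' @param ctx A `resolution_context` whose `do_terms` table is set.
#' @param quiet Suppress the unresolved-term message.
#' @return One-row tibble (`kind`, `primary_id`, `is_surrogate`, `uri`,
#'   `xrefs`, with the match method in the xref comments), or NULL when
#'   unresolved.
#' @export
resolve_disease <- function(term, ctx, quiet = FALSE) {
  do_terms <- ctx$do_terms
  if (is.null(do_terms)) {
    rlang::abort("resolution_context has no disease-term table",
                 class = "scb_validation_error")
  }
  hit <- NULL; method <- NULL
  if (term %in% do_terms$doid) {
    hit <- term; method <- "doid"
  } else {
    nterm <- normalize_term(term)
    labels <- normalize_term(do_terms$label)
    syn_list <- lapply(do_terms$synonyms %||% rep("", nrow(do_terms)),
                       function(s) {
                         if (is.na(s) || !nzchar(s)) character() else
                           normalize_term(strsplit(s, "|", fixed = TRUE)[[1]])
                       })
    exact <- labels == nterm |
      vapply(syn_list, function(s) nterm %in% s, logical(1))
    if (any(exact)) {
      cand <- sort(do_terms$doid[exact])
      hit <- cand[[1]]
      method <- "exact"
    } else {
      sims <- vapply(seq_len(nrow(do_terms)), function(i) {
        max(c(token_jaccard(nterm, labels[[i]]),
              vapply(syn_list[[i]], token_jaccard, numeric(1), a = nterm), 0))
      }, numeric(1))
      ok <- sims >= ctx$disease_threshold
      if (any(ok)) {
        best <- max(sims[ok])
        cand <- sort(do_terms$doid[ok & sims == best])
        hit <- cand[[1]]
        method <- sprintf("token_jaccard=%.3f", best)
      }
    }
  }
  if (is.null(hit)) {
    if (!quiet) rlang::inform(paste0("Unresolved disease term: ", term),
                              class = "scb_unresolved_term")
    return(NULL)
  }
  tibble::tibble(
    kind = "disease", primary_id = hit, is_surrogate = FALSE,
    uri = mint_uri("disease", hit, ctx$base),
    xrefs = list(xref("DO", hit, comments = paste0("match:", method)))
  )
}

#' Resolve an entity with a native primary identifier
#'
#' Drugs use DrugBank IDs, proteins UniProt entry names (matched
#' case-insensitively and stored upper-case), side effects UMLS IDs, and
#' pathways their names.
#'
#' @param kind One of `"drug"`, `"protein"`, `"side_effect"`, `"pathway"`,
#'   `"literature"`.
#' @param primary_id The native identifier.
#' @param ctx A `resolution_context`.
#' @param xrefs Optional cross-reference tibble.
#' @return One-row resolved-entity tibble.
#' @export
resolve_native <- function(kind, primary_id, ctx = resolution_context(),
                           xrefs = NULL) {
  primary_id <- as.character(primary_id)
  if (kind == "protein") primary_id <- toupper(primary_id)
  if (is.null(xrefs)) xrefs <- xref("placeholder", "x")[0, ]
  tibble::tibble(
    kind = kind, primary_id = primary_id, is_surrogate = FALSE,
    uri = mint_uri(kind, primary_id, ctx$base),
    xrefs = list(tibble::as_tibble(xrefs))
  )
}
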