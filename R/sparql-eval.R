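# Evaluation of the parsed SPARQL subset over the triples tibble.
# Solutions are tibbles with one character column per variable; joins give
# bag semantics per the SPARQL algebra for the supported constructs.

match_pattern <- function(tp, tt) {
  keep <- rep(TRUE, nrow(tt))
  if (tp$s$kind == "uri") keep <- keep & tt$subject == tp$s$value
  if (tp$p$kind == "uri") keep <- keep & tt$predicate == tp$p$value
  if (tp$o$kind == "uri") {
    keep <- keep & !tt$is_literal & tt$object == tp$o$value
  } else if (tp$o$kind == "literal") {
    keep <- keep & tt$is_literal & tt$object == tp$o$value
  }
  rows <- tt[keep, ]
  vars <- list()
  for (slot in c("s", "p", "o")) {
    term <- tp[[slot]]
    if (term$kind != "var") next
    col <- switch(slot, s = rows$subject, p = rows$predicate, o = rows$object)
    if (term$value %in% names(vars)) {
      sel <- vars[[term$value]] == col
      vars <- lapply(vars, function(x) x[sel])
      rows <- rows[sel, , drop = FALSE]
    } else {
      vars[[term$value]] <- col
    }
  }
  if (length(vars) == 0) {
    return(tibble::tibble(.match = rep(TRUE, min(nrow(rows), 1L))))
  }
  tibble::as_tibble(vars)
}

join_solutions <- function(a, b, optional = FALSE) {
  if (is.null(a)) return(b)
  common <- intersect(names(a), names(b))
  if (length(common) == 0) {
    if (nrow(b) == 0) {
      if (!optional) return(b[0, ] |> dplyr::cross_join(a[0, ]))
      for (v in names(b)) a[[v]] <- NA_character_
      return(a)
    }
    return(dplyr::cross_join(a, b))
  }
  if (optional) {
    dplyr::left_join(a, b, by = common, relationship = "many-to-many")
  } else {
    dplyr::inner_join(a, b, by = common, relationship = "many-to-many")
  }
}

eval_ggp <- function(elements, tt, sols = NULL) {
  filters <- list()
  for (el in elements) {
    if (el$type == "bgp") {
      for (tp in el$patterns) {
        sols <- join_solutions(sols, match_pattern(tp, tt))
      }
    } else if (el$type == "group") {
      sols <- join_solutions(sols, eval_ggp(el$group, tt))
    } else if (el$type == "union") {
      branches <- lapply(el$groups, eval_ggp, tt = tt)
      sols <- join_solutions(sols, dplyr::bind_rows(branches))
    } else if (el$type == "optional") {
      sols <- join_solutions(sols, eval_ggp(el$group, tt), optional = TRUE)
    } else if (el$type == "filter") {
      filters[[length(filters) + 1L]] <- el$expr
    }
  }
  if (is.null(sols)) sols <- tibble::tibble(.rows = 1L)
  for (f in filters) {
    keep <- eval_sparql_expr(f, sols)$v
    keep[is.na(keep)] <- FALSE
    sols <- sols[as.logical(keep), , drop = FALSE]
  }
  sols
}

eval_sparql_expr <- function(expr, df) {
  if (expr$op == "term") {
    t <- expr$term
    if (t$kind == "var") {
      v <- if (t$value %in% names(df)) df[[t$value]] else
        rep(NA_character_, nrow(df))
      return(list(v = v, num = FALSE))
    }
    if (t$kind == "literal" && isTRUE(t$numeric)) {
      return(list(v = rep(as.numeric(t$value), max(nrow(df), 1L)), num = TRUE))
    }
    return(list(v = rep(t$value, max(nrow(df), 1L)), num = FALSE))
  }
  if (expr$op == "!") {
    l <- eval_sparql_expr(expr$l, df)
    return(list(v = !as.logical(l$v), num = FALSE))
  }
  l <- eval_sparql_expr(expr$l, df)
  r <- eval_sparql_expr(expr$r, df)
  if (expr$op %in% c("&&", "||")) {
    fun <- if (expr$op == "&&") `&` else `|`
    return(list(v = fun(as.logical(l$v), as.logical(r$v)), num = FALSE))
  }
  numeric_cmp <- l$num || r$num || expr$op %in% c("<", ">", "<=", ">=")
  lv <- l$v; rv <- r$v
  if (numeric_cmp) {
    lv <- suppressWarnings(as.numeric(lv))
    rv <- suppressWarnings(as.numeric(rv))
  }
  v <- switch(expr$op,
    "=" = lv == rv, "!=" = lv != rv,
    "<" = lv < rv, ">" = lv > rv, "<=" = lv <= rv, ">=" = lv >= rv
  )
  list(v = v, num = FALSE)
}

#' Run a SPARQL query over a semantic graph
#'
#' Supports the construct subset used by the shipped query templates: basic
#' graph patterns, FILTER, UNION, OPTIONAL, DISTINCT, GROUP BY with COUNT
#' aggregates, and ORDER BY. Unsupported constructs raise a typed
#' unsupported-feature error; malformed queries raise a parse error naming
#' the character position.
#'
#' @param graph A `semantic_graph` (normally materialized first).
#' @param query SPARQL text.
#' @return A tibble of bindings, one column per selected variable.
#' @examples
#' sc <- build_schema()
#' g <- materialize(annotate_worked_example(), sc)
#' run_sparql(g, sparql_template("drug_targets", label = "Troglitazone"))
#' @export
run_sparql <- function(graph, query) {
  ast <- parse_sparql(query)
  sols <- eval_ggp(ast$group, graph$triples)
  internal <- grepl("^\\.", names(sols))
  if (length(ast$aggs) > 0) {
    gb <- ast$group_by
    grouped <- if (length(gb) > 0) dplyr::group_by(sols, dplyr::across(dplyr::all_of(gb)))
               else sols
    summ <- list()
    for (a in ast$aggs) {
      v <- a$var; as_name <- a$as; dist <- a$distinct
      summ[[as_name]] <- if (dist) {
        rlang::expr(dplyr::n_distinct(.data[[!!v]][!is.na(.data[[!!v]])]))
      } else {
        rlang::expr(sum(!is.na(.data[[!!v]])))
      }
    }
    sols <- dplyr::summarise(grouped, !!!summ, .groups = "drop")
    sols <- dplyr::mutate(sols, dplyr::across(
      dplyr::all_of(vapply(ast$aggs, `[[`, "", "as")), as.integer))
    proj_vars <- c(if (!identical(ast$proj, "*")) unlist(ast$proj) else gb,
                   vapply(ast$aggs, `[[`, "", "as"))
  } else {
    proj_vars <- if (identical(ast$proj, "*")) names(sols)[!internal]
                 else unlist(ast$proj)
  }
  missing_vars <- setdiff(proj_vars, names(sols))
  for (v in missing_vars) sols[[v]] <- NA_character_
  out <- sols[, proj_vars, drop = FALSE]
  if (ast$distinct) out <- dplyr::distinct(out)
  if (length(ast$order_by) > 0) {
    exprs <- lapply(ast$order_by, function(ob) {
      col <- out[[ob$var]]
      num <- suppressWarnings(as.numeric(col))
      key <- if (!anyNA(num[!is.na(col)])) num else col
      if (ob$desc) -xtfrm(key) else xtfrm(key)
    })
    out <- out[do.call(order, exprs), , drop = FALSE]
  }
  tibble::as_tibble(out)
}
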