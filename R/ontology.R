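# Minimal GO ontology handling: is_a DAG, shortest-path levels (root =
# level 1), true-path annotation propagation, and level projection.

#' Construct an ontology DAG
#'
#' Builds the `is_a` graph used for level projection.  Roots (terms with
#' no parent) are level 1; `level(t) = 1 + min over parents(level)`, the
#' shortest `is_a` path to a root.
#'
#' @param terms data frame `term_id` and optionally `name`, `namespace`.
#' @param edges data frame `term_id`, `parent_id` (`is_a` edges).
#' @return object of class `"ontology"` with `terms`, `edges`, `graph`,
#'   `roots` and a precomputed `level` per term.
#' @export
ontology_graph <- function(terms, edges) {
  ids <- unique(terms$term_id)
  if (nrow(edges) > 0 &&
    !all(c(edges$term_id, edges$parent_id) %in% ids)) {
    contract_error("edges refer to unknown terms")
  }
  g <- igraph::graph_from_data_frame(
    d = edges[, c("term_id", "parent_id")],
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) contract_error("is_a graph must be acyclic")
  roots <- ids[igraph::degree(g, mode = "out") == 0]
  dist <- igraph::distances(g,
    v = ids, to = roots, mode = "out"
  )
  level <- apply(dist, 1, min) + 1
  if (any(!is.finite(level))) {
    contract_error("every term must reach a root via is_a edges")
  }
  structure(
    list(
      terms = terms, edges = edges, graph = g, roots = roots,
      level = stats::setNames(as.numeric(level), ids)
    ),
    class = "ontology"
  )
}

#' Read a (minimal) OBO ontology
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a`
#' edges; obsolete terms are dropped.  Everything else in the file is
#' ignored.
#'
#' @param path OBO file.
#' @return an [ontology_graph()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(grepl("^\\[", lines)))
  term_rows <- list()
  edge_rows <- list()
  for (b in blocks) {
    if (length(b) == 0 || b[1] != "[Term]") next
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), b,
        value = TRUE
      ))
      if (length(v) == 0) NA_character_ else v
    }
    if (any(grepl("^is_obsolete: true", b))) next
    id <- get1("id")[1]
    term_rows[[length(term_rows) + 1]] <- data.frame(
      term_id = id, name = get1("name")[1],
      namespace = get1("namespace")[1], stringsAsFactors = FALSE
    )
    parents <- sub(" !.*$", "", get1("is_a"))
    parents <- parents[!is.na(parents)]
    if (length(parents) > 0) {
      edge_rows[[length(edge_rows) + 1]] <- data.frame(
        term_id = id, parent_id = parents, stringsAsFactors = FALSE
      )
    }
  }
  terms <- do.call(rbind, term_rows)
  edges <- if (length(edge_rows) > 0) {
    do.call(rbind, edge_rows)
  } else {
    data.frame(
      term_id = character(), parent_id = character(),
      stringsAsFactors = FALSE
    )
  }
  ontology_graph(terms, edges)
}

# All ancestors of a term (including itself) following is_a edges.
.ancestors <- function(ontology, term) {
  igraph::subcomponent(ontology$graph, term, mode = "out")$name
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' A transcript annotated to a term is implicitly annotated to all of the
#' term's ancestors; this materializes that closure.  Terms absent from
#' the ontology are skipped with a warning.
#'
#' @param annotation_map data frame `transcript_id`, `term_id`.
#' @param ontology an [ontology_graph()] object.
#' @return expanded annotation map, duplicates collapsed.
#' @export
propagate_annotations <- function(annotation_map, ontology) {
  known <- names(ontology$level)
  miss <- setdiff(unique(annotation_map$term_id), known)
  if (length(miss) > 0) {
    warning(
      "skipping ", length(miss),
      " annotation term(s) absent from the ontology: ",
      paste(utils::head(miss, 5), collapse = ", ")
    )
    annotation_map <- annotation_map[annotation_map$term_id %in% known, ]
  }
  anc <- lapply(
    stats::setNames(nm = unique(annotation_map$term_id)),
    function(t) .ancestors(ontology, t)
  )
  n_anc <- lengths(anc[annotation_map$term_id])
  out <- data.frame(
    transcript_id = rep(annotation_map$transcript_id, n_anc),
    term_id = unlist(anc[annotation_map$term_id], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Project annotations to a fixed ontology level
#'
#' Replaces each annotation by the term's ancestor set at the requested
#' level (root = level 1).  Terms already above (shallower than) the
#' requested level map to nothing; duplicates per transcript collapse;
#' annotation terms missing from the ontology are skipped with a warning.
#'
#' @param annotation_map data frame `transcript_id`, `term_id`.
#' @param ontology an [ontology_graph()] object.
#' @param level positive integer level.
#' @return annotation map whose terms all sit at `level`.
#' @export
project_to_level <- function(annotation_map, ontology, level) {
  stopifnot_scalar_number(level, "level", min = 1)
  known <- names(ontology$level)
  miss <- setdiff(unique(annotation_map$term_id), known)
  if (length(miss) > 0) {
    warning(
      "skipping ", length(miss),
      " annotation term(s) absent from the ontology: ",
      paste(utils::head(miss, 5), collapse = ", ")
    )
    annotation_map <- annotation_map[annotation_map$term_id %in% known, ]
  }
  at_level <- lapply(
    stats::setNames(nm = unique(annotation_map$term_id)),
    function(t) {
      a <- .ancestors(ontology, t)
      a[ontology$level[a] == level & ontology$level[t] >= level]
    }
  )
  n <- lengths(at_level[annotation_map$term_id])
  out <- data.frame(
    transcript_id = rep(annotation_map$transcript_id, n),
    term_id = unlist(at_level[annotation_map$term_id], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  unique(out)
}
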