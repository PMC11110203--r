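# Rooted term DAG with typed edges (is_a / part_of) and optional
# gene -> term annotations.  Edges point child -> parent.

new_ontology <- function(terms, edges, root, annotations = list()) {
  stopifnot(all(edges$child %in% terms), all(edges$parent %in% terms))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) abort("ontology format error: term graph contains a cycle")
  structure(list(terms = terms, edges = edges, root = root, annotations = annotations),
            class = "plaquekg_ontology")
}

#' @export
print.plaquekg_ontology <- function(x, ...) {
  cat(sprintf("<plaquekg_ontology> %d terms, %d edges, root %s, %d annotated genes\n",
              length(x$terms), nrow(x$edges), x$root, length(x$annotations)))
  invisible(x)
}

#' Ancestors of a term (transitive closure over is_a and part_of)
#'
#' @param ontology A `plaquekg_ontology`.
#' @param term A term id.
#' @param include_self Include the term itself.
#' @return Character vector of ancestor term ids.
#' @export
ontology_ancestors <- function(ontology, term, include_self = FALSE) {
  if (!term %in% ontology$terms) abort(sprintf("unknown term '%s'", term))
  parents_of <- split(ontology$edges$parent, ontology$edges$child)
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (include_self) unique(c(term, seen)) else seen
}

ontology_leaves <- function(ontology) {
  setdiff(ontology$terms, unique(ontology$edges$parent))
}
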