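#' Single-source shortest paths on the fused graph
#'
#' Dijkstra over the per-edge traversal lengths.  Unreachable nodes get
#' `Inf`.
#'
#' @param kg Fused igraph from [fuse_graph()].
#' @param source Bare node id (symptom, plaque or gene name).
#' @return Named numeric vector of path lengths over all vertices (bare
#'   ids).
#' @export
kg_shortest_paths <- function(kg, source) {
  nm <- igraph::V(kg)$name
  src <- nm[strip_id(nm) == source]
  if (length(src) == 0) abort(sprintf("input error: unknown source node '%s'", source))
  d <- igraph::distances(kg, v = src[1], weights = igraph::E(kg)$length,
                         algorithm = "dijkstra")[1, ]
  names(d) <- strip_id(nm)
  d
}

#' Point-to-point and point-to-network topology features
#'
#' For every symptom the vector of shortest-path lengths to each plaque
#' node is its topology profile.  `topo_dist` is the symptom-to-plaque
#' path length itself (point-to-point); `topo_euclid` is the Euclidean
#' distance between the symptom's profile and the centroid of all symptom
#' profiles (point-to-network).  Infinite lengths are replaced by twice
#' the largest finite length before profiling, and affected symptoms are
#' flagged.
#'
#' @param kg Fused igraph.
#' @param symptoms,plaque_ids Bare ids; default all in the graph.
#' @return Tibble with one row per (symptom, plaque): `topo_dist`,
#'   `topo_euclid`, `disconnected` flag.
#' @export
topo_features <- function(kg, symptoms = kg_symptoms(kg), plaque_ids = kg_plaques(kg)) {
  if (length(plaque_ids) == 0) abort("input error: no plaque nodes")
  D <- matrix(Inf, length(symptoms), length(plaque_ids),
              dimnames = list(symptoms, plaque_ids))
  for (s in symptoms) {
    d <- kg_shortest_paths(kg, s)
    D[s, ] <- d[plaque_ids]
  }
  finite <- D[is.finite(D)]
  cap <- if (length(finite) > 0) 2 * max(finite) else 1
  disconnected <- rowSums(is.finite(D)) == 0
  Dc <- D
  Dc[!is.finite(Dc)] <- cap
  centroid <- colMeans(Dc)
  euclid <- sqrt(rowSums((Dc - matrix(centroid, nrow(Dc), ncol(Dc), byrow = TRUE))^2))
  tidyr::expand_grid(symptom = symptoms, plaque = plaque_ids) |>
    mutate(
      topo_dist = Dc[cbind(.data$symptom, .data$plaque)],
      topo_euclid = euclid[.data$symptom],
      disconnected = disconnected[.data$symptom]
    )
}
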