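# Shared fixtures and independent oracles for the test suite.

toy_records <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    symptoms = list(c("s1", "s2"), "s1", "s2"),
    plaques = list("calcified", "calcified", character(0))
  )
}

# tiny igraph with named vertices and unit traversal lengths
mini_graph <- function(edges, lengths = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$length <- lengths %||% rep(1, igraph::ecount(g))
  igraph::E(g)$kind <- "cooccurrence"
  igraph::V(g)$kind <- "symptom"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bellman-Ford single-source shortest paths, edge-list relaxation
bellman_ford <- function(edges, lengths, nodes, source) {
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[source] <- 0
  for (iter in seq_len(length(nodes) - 1)) {
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1]; v <- edges[i, 2]; w <- lengths[i]
      if (d[u] + w < d[v]) d[v] <- d[u] + w
      if (d[v] + w < d[u]) d[u] <- d[v] + w
    }
  }
  d
}

# Exhaustive-path Wang semantic contribution: max over all upward paths of
# the product of edge weights.
brute_svalues <- function(ontology, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  edges <- ontology$edges
  out <- new.env(parent = emptyenv())
  assign(term, 1, out)
  walk <- function(t, val) {
    up <- edges[edges$child == t, ]
    for (i in seq_len(nrow(up))) {
      v <- val * weights[[up$relation[i]]]
      p <- up$parent[i]
      if (v > get0(p, out, ifnotfound = -Inf)) assign(p, v, out)
      walk(p, v)
    }
  }
  walk(term, 1)
  vals <- mget(ls(out), out)
  stats::setNames(as.numeric(vals), names(vals))
}

# random small ontology DAG for oracle tests
random_ontology <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n_terms))
  edges <- purrr::map_dfr(seq(2, n_terms), function(i) {
    n_par <- sample(1:min(2, i - 1), 1)
    parents <- sample(terms[seq_len(i - 1)], n_par)
    tibble::tibble(child = terms[i], parent = parents,
                   relation = sample(c("is_a", "part_of"), n_par, replace = TRUE))
  })
  plaquekg:::new_ontology(terms = terms, edges = edges, root = terms[1])
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

# brute-force pairwise co-occurrence counter over records
brute_cooccurrence <- function(records) {
  counts <- list()
  for (i in seq_len(nrow(records))) {
    items <- sort(unique(c(records$symptoms[[i]], records$plaques[[i]])))
    if (length(items) < 2) next
    cmb <- utils::combn(items, 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

# small fused toy graph used across feature/labeling tests
toy_fused_graph <- function() {
  records <- tibble::tibble(
    patient_id = sprintf("p%d", 1:6),
    symptoms = list(c("s1", "s2"), "s1", c("s1", "s3"), "s2", "s3", "s1"),
    plaques = list("calcified", "calcified", "mixed", character(0), "mixed", "calcified")
  )
  cn <- build_clinical_network(records)
  symptom_sets <- list(s1 = c("g1", "g2"), s2 = "g3", s3 = c("g2", "g4"))
  plaque_sets <- list(calcified = c("g1", "g4"), mixed = "g3")
  ppin <- tibble::tibble(gene1 = c("g1", "g2", "g3"), gene2 = c("g2", "g3", "g4"),
                         combined_score = c(700L, 500L, 900L))
  suppressWarnings(fuse_graph(cn, symptom_sets, plaque_sets, ppin))
}
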