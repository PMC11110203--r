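#' Read and write patient record tables
#'
#' The record table is a TSV with columns `patient_id`, `symptoms`
#' (semicolon-separated ids, possibly empty) and `plaques`
#' (semicolon-separated subset of calcified/noncalcified/mixed); any further
#' numeric columns are kept as covariates.  Writing then reading a record
#' table is an identity.
#'
#' @param path File path.
#' @return A tibble with list-columns `symptoms` and `plaques`.
#' @export
read_records <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    symptoms = readr::col_character(),
    plaques = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("patient_id", "symptoms", "plaques")
  if (!all(need %in% names(df))) {
    abort(sprintf("record parse error: missing column(s) %s",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  }
  split_field <- function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  symptoms <- map(df$symptoms, split_field)
  plaques <- map(df$plaques, split_field)
  for (i in seq_along(plaques)) {
    bad <- setdiff(plaques[[i]], PLAQUE_LEVELS)
    if (length(bad) > 0) {
      abort(sprintf("record parse error at line %d: unknown plaque label '%s'",
                    i + 1L, bad[1]))
    }
    if (anyDuplicated(symptoms[[i]])) {
      warn(sprintf("duplicate symptom ids at line %d collapsed", i + 1L))
      symptoms[[i]] <- unique(symptoms[[i]])
    }
  }
  out <- tibble(patient_id = df$patient_id, symptoms = symptoms, plaques = plaques)
  covar <- setdiff(names(df), need)
  if (length(covar) > 0) out <- dplyr::bind_cols(out, df[covar])
  out
}

#' @param records A record tibble as returned by [read_records()] or
#'   [generate_cohort()].
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  df <- records
  df$symptoms <- map_chr(records$symptoms, paste, collapse = ";")
  df$plaques <- map_chr(records$plaques, paste, collapse = ";")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' then gene ids.
#'
#' @param path File path.
#' @return Named list of character gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort(sprintf("GMT parse error: line '%s' has fewer than 3 fields", substr(l, 1, 40)))
    parts[-(1:2)]
  })
  names(sets) <- map_chr(lines, ~ strsplit(.x, "\t", fixed = TRUE)[[1]][1])
  sets
}

#' @param sets Named list of gene-id vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- map_chr(names(sets), function(id) {
    paste(c(id, id, sets[[id]]), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write interaction edge lists
#'
#' Three-column TSV (`gene1`, `gene2`, `combined_score`) in the style of
#' bulk interactome downloads.  Edges below `min_score` are dropped and
#' the dropped count reported; the default threshold retains combined
#' scores >= 400.
#'
#' @param path File path.
#' @param min_score Minimum combined score retained (inclusive).
#' @return A tibble of retained edges with attribute `dropped` holding the
#'   number of edges removed by the threshold.
#' @export
read_ppin <- function(path, min_score = 400) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("gene1", "gene2", "combined_score") %in% names(df))) {
    abort("PPIN parse error: expected columns gene1, gene2, combined_score")
  }
  score_num <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score_num) | score_num != round(score_num))
  if (length(bad) > 0) {
    abort(sprintf("PPIN parse error at line %d: non-integer score '%s'",
                  bad[1] + 1L, df$combined_score[bad[1]]))
  }
  df$combined_score <- as.integer(score_num)
  keep <- df$combined_score >= min_score
  dropped <- sum(!keep)
  if (dropped > 0) inform(sprintf("read_ppin: dropped %d edge(s) below combined score %d", dropped, min_score))
  out <- as_tibble(df[keep, ])
  attr(out, "dropped") <- dropped
  out
}

#' @param ppin Interaction edge tibble.
#' @rdname read_ppin
#' @export
write_ppin <- function(ppin, path) {
  readr::write_tsv(ppin[, c("gene1", "gene2", "combined_score")], path)
  invisible(path)
}

#' Read and write a minimal OBO term file
#'
#' Supports `[Term]` stanzas with `id`, `name`, `is_a` and
#' `relationship: part_of` tags only.  The term graph must be an acyclic
#' rooted DAG.
#'
#' @param path File path.
#' @return A `plaquekg_ontology`.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path)
  terms <- character(0)
  edges <- list()
  cur <- NULL
  flush_edges <- function() {}
  for (l in lines) {
    l <- trimws(l)
    if (l == "[Term]") {
      cur <- NULL
    } else if (startsWith(l, "id:")) {
      cur <- trimws(sub("^id:", "", l))
      terms <- c(terms, cur)
    } else if (startsWith(l, "is_a:")) {
      if (is.null(cur)) abort("OBO format error: is_a before id")
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
      edges[[length(edges) + 1]] <- tibble(child = cur, parent = parent, relation = "is_a")
    } else if (startsWith(l, "relationship:")) {
      body <- trimws(sub("!.*$", "", sub("^relationship:", "", l)))
      parts <- strsplit(body, "\\s+")[[1]]
      if (length(parts) != 2 || parts[1] != "part_of") {
        abort(sprintf("OBO format error: unsupported relationship '%s'", body))
      }
      edges[[length(edges) + 1]] <- tibble(child = cur, parent = parts[2], relation = "part_of")
    }
  }
  edges <- if (length(edges) > 0) bind_rows(edges) else tibble(child = character(0), parent = character(0), relation = character(0))
  missing_parents <- setdiff(edges$parent, terms)
  if (length(missing_parents) > 0) {
    abort(sprintf("OBO format error: parent term '%s' has no stanza", missing_parents[1]))
  }
  roots <- setdiff(terms, edges$child)
  if (length(roots) == 0) abort("OBO format error: no root term (cycle?)")
  new_ontology(terms = terms, edges = edges, root = roots[1])
}

#' @param ontology A `plaquekg_ontology`.
#' @rdname read_obo
#' @export
write_obo <- function(ontology, path) {
  out <- c("format-version: 1.2", "")
  for (t in ontology$terms) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", t))
    e <- ontology$edges[ontology$edges$child == t, ]
    for (i in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[i] == "is_a") paste0("is_a: ", e$parent[i])
               else paste0("relationship: part_of ", e$parent[i]))
    }
    out <- c(out, "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Read and write gene-to-term annotation tables
#'
#' Two-column TSV (`gene`, `term`), one row per annotation.
#'
#' @param path File path.
#' @return Named list gene -> character vector of term ids.
#' @export
read_gene2term <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("gene", "term") %in% names(df))) {
    abort("annotation parse error: expected columns gene, term")
  }
  lapply(split(df$term, df$gene), function(x) sort(unique(x)))
}

#' @param annotations Named list gene -> term ids.
#' @rdname read_gene2term
#' @export
write_gene2term <- function(annotations, path) {
  df <- tibble(
    gene = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Build the clinical co-occurrence network
#'
#' Nodes are every observed symptom and plaque type; two nodes are joined
#' whenever they appear in the same patient, and the edge weight is the
#' number of patients in which the pair co-occurs (each patient contributes
#' at most one to any edge).
#'
#' @param records Record tibble.
#' @return A `clinical_network`: list with `nodes` (id, kind, patient count)
#'   and `edges` (from, to, weight) tibbles.
#' @export
build_clinical_network <- function(records) {
  if (nrow(records) == 0) abort("input error: empty record list")
  items <- map2(records$symptoms, records$plaques, ~ c(unique(.x), unique(.y)))
  kind_of <- c()
  for (i in seq_along(items)) {
    for (s in unique(records$symptoms[[i]])) kind_of[s] <- "symptom"
    for (p in unique(records$plaques[[i]])) kind_of[p] <- "plaque"
  }
  pair_list <- keep(items, ~ length(.x) >= 2)
  edges <- if (length(pair_list) > 0) {
    pairs <- purrr::map_dfr(pair_list, function(it) {
      it <- sort(it)
      cmb <- utils::combn(it, 2)
      tibble(from = cmb[1, ], to = cmb[2, ])
    })
    dplyr::count(pairs, .data$from, .data$to, name = "weight")
  } else {
    tibble(from = character(0), to = character(0), weight = integer(0))
  }
  counts <- table(unlist(map(items, unique)))
  nodes <- tibble(
    id = names(kind_of), kind = unname(kind_of),
    count = as.integer(counts[names(kind_of)])
  ) |> arrange(.data$kind, .data$id)
  structure(list(nodes = nodes, edges = as_tibble(edges)), class = "clinical_network")
}

#' @export
print.clinical_network <- function(x, ...) {
  cat(sprintf("<clinical_network> %d nodes (%d symptoms, %d plaques), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "symptom"),
              sum(x$nodes$kind == "plaque"), nrow(x$edges)))
  invisible(x)
}

#' Traversal lengths for the fused knowledge graph
#'
#' Shortest-path computations need a positive length per edge.
#' Co-occurrence edges shrink with weight (`1/log(1 + weight)`: more
#' shared patients means closer), interaction edges shrink with confidence
#' (`1 - score/1000 + 0.001`, floored positive), and annotation edges have
#' unit length.  Set `weighted = FALSE` for unit lengths on every edge.
#'
#' @param cooccurrence,interaction,annotation Functions mapping the raw
#'   edge weight to a traversal length.
#' @return A list of three length functions.
#' @export
edge_lengths <- function(cooccurrence = function(w) 1 / log(1 + w),
                         interaction = function(score) 1 - score / 1000 + 0.001,
                         annotation = function(w) 1.0) {
  list(cooccurrence = cooccurrence, interaction = interaction, annotation = annotation)
}

#' Fuse the clinical network, annotation sets and interactome
#'
#' Merges the three layers into one undirected heterogeneous graph:
#' co-occurrence edges between clinical nodes, annotation edges from each
#' symptom or plaque to its genes, and interaction edges between genes
#' (combined score >= 400 enforced).  Vertex names are namespaced by kind;
#' every edge carries its kind, raw weight and traversal length.
#'
#' @param clinical A `clinical_network`.
#' @param symptom_sets,plaque_sets Named lists of gene-id vectors.
#' @param ppin Interaction edge tibble (already score-filtered).
#' @param lengths An [edge_lengths()] specification.
#' @param weighted If `FALSE`, all traversal lengths are 1.
#' @return An igraph object with vertex attributes `kind` and edge
#'   attributes `kind`, `weight`, `length`.
#' @export
fuse_graph <- function(clinical, symptom_sets, plaque_sets, ppin,
                       lengths = edge_lengths(), weighted = TRUE) {
  if (nrow(ppin) > 0 && any(ppin$combined_score < 400)) {
    abort("interaction edges must have combined score >= 400; filter with read_ppin()")
  }
  kind_prefix <- function(id, kind) vapply(id, function(x) node_id(kind, x), character(1))
  cn <- clinical$nodes
  cn_ids <- kind_prefix(cn$id, "symptom")
  cn_ids[cn$kind == "plaque"] <- kind_prefix(cn$id[cn$kind == "plaque"], "plaque")

  anno_edges <- bind_rows(
    purrr::imap_dfr(symptom_sets, ~ tibble(from = node_id("symptom", .y), to = kind_prefix(.x, "gene"))),
    purrr::imap_dfr(plaque_sets, ~ tibble(from = node_id("plaque", .y), to = kind_prefix(.x, "gene")))
  )
  no_set <- setdiff(cn$id[cn$kind == "symptom"], names(symptom_sets))
  if (length(no_set) > 0) {
    warn(sprintf("fusion: %d clinical symptom(s) have no gene set (%s)",
                 length(no_set), paste(head(no_set, 3), collapse = ", ")))
  }
  ppin_genes <- unique(c(ppin$gene1, ppin$gene2))
  anno_genes <- unique(strip_id(anno_edges$to))
  orphan <- setdiff(anno_genes, ppin_genes)
  if (length(orphan) > 0 && nrow(ppin) > 0) {
    warn(sprintf("fusion: %d annotated gene(s) absent from the interactome kept as isolated nodes", length(orphan)))
  }

  cw <- function(x) if (weighted) x else rep(1, length(x))
  edges <- bind_rows(
    tibble(from = kind_prefix_lookup(clinical$edges$from, cn$id, cn_ids),
           to = kind_prefix_lookup(clinical$edges$to, cn$id, cn_ids),
           kind = "cooccurrence", weight = as.numeric(clinical$edges$weight),
           length = lengths$cooccurrence(cw(clinical$edges$weight))),
    tibble(from = anno_edges$from, to = anno_edges$to, kind = "annotation",
           weight = 1, length = rep(lengths$annotation(1), nrow(anno_edges))),
    tibble(from = kind_prefix(ppin$gene1, "gene"), to = kind_prefix(ppin$gene2, "gene"),
           kind = "interaction", weight = as.numeric(ppin$combined_score),
           length = lengths$interaction(cw(ppin$combined_score)))
  )
  all_ids <- unique(c(cn_ids, edges$from, edges$to, kind_prefix(ppin_genes, "gene")))
  vertices <- tibble(name = all_ids, kind = unname(id_kind(all_ids)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  stopifnot(all(igraph::E(g)$length > 0))
  g
}

kind_prefix_lookup <- function(ids, raw, prefixed) prefixed[match(ids, raw)]

#' Vertices of a fused graph by kind
#'
#' @param kg Fused igraph from [fuse_graph()].
#' @return Character vector of bare (unprefixed) ids.
#' @export
kg_symptoms <- function(kg) strip_id(igraph::V(kg)$name[igraph::V(kg)$kind == "symptom"])

#' @rdname kg_symptoms
#' @export
kg_plaques <- function(kg) strip_id(igraph::V(kg)$name[igraph::V(kg)$kind == "plaque"])

#' @rdname kg_symptoms
#' @export
kg_genes <- function(kg) strip_id(igraph::V(kg)$name[igraph::V(kg)$kind == "gene"])
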